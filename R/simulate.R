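# Seeded synthetic-data generators. Every input the toolkit consumes can
# be generated here with embedded ground truth, so the full pipeline is
# testable without any external data. Generators can also emit the same
# file formats the readers consume.

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Fixture specification for the synthetic generators
#'
#' Defaults emulate a broad-panel profiling campaign: a 401-assay wild-type
#' human panel screened at 1 uM, a compound collection mixing selective
#' compounds (small planted active sets, follow-up K_D in the potent
#' range), promiscuous compounds (large active sets) and inactives, a
#' 17-line growth screen, and 49-point flux time series (0-96 h every 2 h).
#'
#' @param seed integer seed; the same spec always yields byte-identical
#'   outputs.
#' @param n_compounds number of compounds (default 60).
#' @param n_kinases panel size (default 401).
#' @param fraction_selective,fraction_promiscuous,fraction_inactive mixture
#'   weights, must sum to 1 (defaults 0.4 / 0.3 / 0.3).
#' @param active_size_range planted active-set size for selective
#'   compounds (default 1-8 kinases).
#' @param promiscuous_size_range planted active-set size for promiscuous
#'   compounds (default 30-60).
#' @param kd_range_nM K_D range for selective compounds' active kinases
#'   (default 10-80 nM, within the potency threshold).
#' @param poc_noise_sd truncated-normal SD of PoC noise in percent
#'   (default 2).
#' @param n_lines cell lines in the growth screen (default 17).
#' @param growth_noise_sd log-normal SD of count noise (default 0.05).
#' @param flux_times time grid in hours (default `seq(0, 96, by = 2)`).
#' @param flux_amplitude planted percent-flux amplitude for hits
#'   (default 30).
#' @param flux_noise_sd additive noise SD on the percent-flux signal
#'   (default 1).
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_compounds = 60, n_kinases = 401,
                         fraction_selective = 0.4,
                         fraction_promiscuous = 0.3,
                         fraction_inactive = 0.3,
                         active_size_range = c(1, 8),
                         promiscuous_size_range = c(30, 60),
                         kd_range_nM = c(10, 80),
                         poc_noise_sd = 2,
                         n_lines = 17, growth_noise_sd = 0.05,
                         flux_times = seq(0, 96, by = 2),
                         flux_amplitude = 30, flux_noise_sd = 1) {
  w <- c(fraction_selective, fraction_promiscuous, fraction_inactive)
  if (abs(sum(w) - 1) > 1e-8) abort("mixture weights must sum to 1")
  if (max(promiscuous_size_range) > n_kinases ||
      max(active_size_range) > n_kinases) {
    abort("planted active-set size exceeds the panel size")
  }
  structure(
    list(seed = as.integer(seed), n_compounds = n_compounds,
         n_kinases = n_kinases, fraction_selective = fraction_selective,
         fraction_promiscuous = fraction_promiscuous,
         fraction_inactive = fraction_inactive,
         active_size_range = active_size_range,
         promiscuous_size_range = promiscuous_size_range,
         kd_range_nM = kd_range_nM, poc_noise_sd = poc_noise_sd,
         n_lines = n_lines, growth_noise_sd = growth_noise_sd,
         flux_times = flux_times, flux_amplitude = flux_amplitude,
         flux_noise_sd = flux_noise_sd),
    class = "fixture_spec"
  )
}

# truncated-normal draw in [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic profiling campaign with ground truth
#'
#' Builds a panel, a PoC matrix at 1 uM, K_D follow-up records for
#' sub-cutoff kinases (mirroring the follow-up workflow), and a truth
#' table. Selective compounds receive a small planted active set with PoC
#' drawn below the 10% cutoff (base 5, truncated to stay below) and potent
#' K_D values; promiscuous compounds receive large active sets; inactive
#' compounds stay near 95 PoC everywhere. By construction each compound's
#' S10 equals (planted active count) / (panel size), and the truth table
#' records whether it should pass the inclusion decision.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory: when given, writes `panel.tsv`,
#'   `poc.csv`, `kd.tsv`, `compounds.smi` and `truth.tsv` there.
#' @return list with `panel`, `matrix` (a [poc_matrix()]), `kd`,
#'   `compounds`, `truth` (tibble: `compound_id`, `class`, `n_active`,
#'   `active_set` list column, `s10_true`, `should_pass`), and `paths`
#'   when `dir` was given.
#' @export
gen_profiles <- function(spec = fixture_spec(), dir = NULL) {
  with_seed(spec$seed, {
    kinases <- sprintf("KIN%03d", seq_len(spec$n_kinases))
    panel <- kinase_panel(
      tibble(
        kinase = kinases,
        family = rep_len(KINASE_FAMILIES, spec$n_kinases),
        is_wild_type = TRUE, is_human = TRUE
      ),
      concentration = 1, name = "synthetic-panel"
    )
    n <- spec$n_compounds
    classes <- rep(
      c("selective", "promiscuous", "inactive"),
      times = round(n * c(spec$fraction_selective, spec$fraction_promiscuous,
                          spec$fraction_inactive))
    )
    classes <- rep_len(classes, n)
    ids <- sprintf("CMP%03d", seq_len(n))
    compounds <- tibble(
      id = ids,
      smiles = strrep("C", 1 + seq_len(n)),
      source = "synthetic", screen_panel = "synthetic-panel"
    )
    truth_rows <- list()
    poc_rows <- list()
    kd_rows <- list()
    for (i in seq_len(n)) {
      cls <- classes[i]
      n_act <- switch(cls,
        selective = sample(spec$active_size_range[1]:spec$active_size_range[2], 1),
        promiscuous = sample(spec$promiscuous_size_range[1]:spec$promiscuous_size_range[2], 1),
        inactive = 0L
      )
      active <- if (n_act > 0) sort(sample(kinases, n_act)) else character()
      poc <- rnorm_trunc(spec$n_kinases, 95, spec$poc_noise_sd, 15, 200)
      poc[match(active, kinases)] <-
        rnorm_trunc(n_act, 5, spec$poc_noise_sd, 0, 9.5)
      poc_rows[[i]] <- tibble(compound_id = ids[i], kinase = kinases,
                              poc = poc)
      if (n_act > 0) {
        kd <- if (cls == "selective") {
          runif(n_act, spec$kd_range_nM[1], spec$kd_range_nM[2])
        } else {
          runif(n_act, 10, 500)
        }
        kd_rows[[i]] <- tibble(compound = ids[i], kinase = active,
                               kd_nM = round(kd, 1))
      }
      s10_true <- n_act / spec$n_kinases
      should_pass <- cls == "selective" && s10_true < 0.025 &&
        n_act > 0 && any(kd_rows[[i]]$kd_nM < 100)
      truth_rows[[i]] <- tibble(
        compound_id = ids[i], class = cls, n_active = n_act,
        active_set = list(active), s10_true = s10_true,
        should_pass = should_pass
      )
    }
    matrix <- poc_matrix(dplyr::bind_rows(poc_rows), panel)
    kd <- if (length(kd_rows)) dplyr::bind_rows(kd_rows) else
      tibble(compound = character(), kinase = character(), kd_nM = double())
    truth <- dplyr::bind_rows(truth_rows)
    out <- list(panel = panel, matrix = matrix, kd = kd,
                compounds = compounds, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      paths <- list(
        panel = file.path(dir, "panel.tsv"),
        poc = file.path(dir, "poc.csv"),
        kd = file.path(dir, "kd.tsv"),
        compounds = file.path(dir, "compounds.smi"),
        truth = file.path(dir, "truth.tsv")
      )
      write_panel(panel, paths$panel)
      write_poc_matrix(matrix, paths$poc)
      write_kd_table(kd, paths$kd)
      write_compounds(compounds, paths$compounds)
      readr::write_tsv(
        truth |> dplyr::mutate(active_set = map_chr(.data$active_set, paste,
                                                    collapse = ";")),
        paths$truth, progress = FALSE
      )
      out$paths <- paths
    }
    out
  })
}

#' Toy molecules exercising the demonstration chemotype catalog
#'
#' A fixed, deterministic list of structures spanning the common
#' hinge-binder scaffolds (indazole, oxindole, quinazoline,
#' 4-anilino-quinazoline, quinoline, pyrimidines) plus an alkane decoy
#' with no hinge binder. `expected_bin` records each structure's bin under
#' the shipped demonstration catalog, including the priority resolution
#' for multi-match structures (the 4-anilino-quinazoline outranks the
#' plain quinazoline and pyrimidine bins).
#'
#' @return tibble with columns `id`, `smiles`, `expected_bin`.
#' @export
toy_molecules <- function() {
  tibble::tribble(
    ~id, ~smiles, ~expected_bin,
    "indazole",       "c1ccc2[nH]ncc2c1",                "indazole",
    "oxindole",       "O=C1Cc2ccccc2N1",                 "oxindole",
    "oxindole-drug",  "CCN(CC)CCNC(=O)c1c(C)[nH]c(C=C2C(=O)Nc3ccccc32)c1C", "oxindole",
    "quinazoline",    "c1ncc2ccccc2n1",                  "quinazoline",
    "anilinoquinazoline", "c1ccc(Nc2ncnc3ccccc23)cc1",   "4-anilino-quinazoline",
    "quinoline",      "c1ccc2ncccc2c1",                  "quinoline",
    "pyrimidine",     "c1cncnc1",                        "pyrimidine",
    "aminopyrimidine", "Nc1ncccn1",                      "2-aminopyrimidine",
    "alkane-decoy",   "CCCCCC",                          "other"
  )
}

#' Generate a synthetic growth screen with ground truth
#'
#' Control counts grow from a common seeding density by a per-line number
#' of doublings; planted effects scale the treated endpoint count to hit a
#' target GR (broad compounds: GR 0.5 on every line; line-dependent
#' compounds: GR 0.15 on three randomly chosen lines, vehicle-like
#' elsewhere; inactive compounds: GR 1 everywhere). Log-normal
#' multiplicative noise of SD `growth_noise_sd` is applied to the treated
#' counts; at zero noise the planted labels are recovered exactly by
#' [classify_growth_response()].
#'
#' @param spec a [fixture_spec()].
#' @param n_per_class compounds per response class (default 5).
#' @return list with `records` (tibble `cell_line`, `compound_id`, `x0`,
#'   `x`, `x_ctrl`) and `truth` (tibble `compound_id`, `class`).
#' @export
gen_growth_screen <- function(spec = fixture_spec(), n_per_class = 5) {
  with_seed(spec$seed + 1L, {
    lines <- sprintf("LINE%02d", seq_len(spec$n_lines))
    doublings <- runif(spec$n_lines, 1.5, 4)
    x0 <- 1000
    x_ctrl <- x0 * 2^doublings
    classes <- rep(c("inactive", "broad", "line_dependent"),
                   each = n_per_class)
    ids <- sprintf("GRW%03d", seq_along(classes))
    rows <- list()
    for (i in seq_along(ids)) {
      gr_target <- rep(1, spec$n_lines)
      if (classes[i] == "broad") {
        gr_target[] <- 0.5
      } else if (classes[i] == "line_dependent") {
        gr_target[sample(spec$n_lines, 3)] <- 0.15
      }
      # invert the GR formula: x = x0 * 2^(log2(gr+1) * log2(x_ctrl/x0))
      x <- x0 * 2^(log2(gr_target + 1) * log2(x_ctrl / x0))
      if (spec$growth_noise_sd > 0) {
        x <- x * exp(rnorm(spec$n_lines, 0, spec$growth_noise_sd))
      }
      rows[[i]] <- tibble(cell_line = lines, compound_id = ids[i],
                          x0 = x0, x = x, x_ctrl = x_ctrl)
    }
    list(records = dplyr::bind_rows(rows),
         truth = tibble(compound_id = ids, class = classes))
  })
}

#' Generate synthetic autophagic-flux series with ground truth
#'
#' Builds vehicle (flat with slight drift), positive-control (early drop,
#' then low) and compound GFP/RFP ratio series on a common time grid. Hits
#' carry a planted run of `flux_amplitude` percent aberration (above the
#' 20% threshold) lasting `run_length >= 5` points in a random direction;
#' decoys carry either a 4-point run at the same amplitude or a long run
#' at sub-threshold amplitude, and nulls stay flat. At zero noise the
#' planted labels are exactly what [autophagy_hit_call()] recovers.
#'
#' @param spec a [fixture_spec()].
#' @param n_hits,n_decoys,n_nulls compounds per group (defaults 4, 4, 4).
#' @return list with `flux` (long tibble `compound_id`, `time_h`,
#'   `gfp_rfp_ratio`, `role`) and `truth` (tibble `compound_id`, `is_hit`,
#'   `direction`, `run_start`, `run_length`).
#' @export
gen_flux_screen <- function(spec = fixture_spec(), n_hits = 4, n_decoys = 4,
                            n_nulls = 4) {
  with_seed(spec$seed + 2L, {
    times <- spec$flux_times
    nt <- length(times)
    if (nt < 9) abort("flux time grid too short for planted runs")
    vehicle <- 1 - 0.0005 * times
    # inducer control drops fast from the first scan, then plateaus low
    control <- pmax(0.35, 0.9 - 0.06 * times)
    span <- control - vehicle
    groups <- c(rep("hit", n_hits), rep("decoy", n_decoys),
                rep("null", n_nulls))
    ids <- sprintf("FLX%03d", seq_along(groups))
    flux_rows <- list(
      tibble(compound_id = "DMSO", time_h = times, gfp_rfp_ratio = vehicle,
             role = "vehicle"),
      tibble(compound_id = "TORIN1", time_h = times,
             gfp_rfp_ratio = control, role = "positive_control")
    )
    truth_rows <- list()
    for (i in seq_along(ids)) {
      pct <- rep(0, nt)
      grp <- groups[i]
      if (grp == "hit") {
        len <- sample(5:8, 1)
        start <- sample(seq_len(nt - len + 1), 1)
        dir <- sample(c(1, -1), 1)
        pct[start:(start + len - 1)] <- dir * spec$flux_amplitude
        truth_rows[[i]] <- tibble(
          compound_id = ids[i], is_hit = TRUE,
          direction = if (dir > 0) "induced" else "reduced",
          run_start = start, run_length = len
        )
      } else if (grp == "decoy") {
        if (i %% 2 == 0) {
          len <- 4L  # one point short of a qualifying run
          start <- sample(seq_len(nt - 6), 1)
          pct[start:(start + len - 1)] <- spec$flux_amplitude
        } else {
          start <- sample(seq_len(nt - 10), 1)
          pct[start:(start + 7)] <- 15  # long but sub-threshold
        }
        truth_rows[[i]] <- tibble(compound_id = ids[i], is_hit = FALSE,
                                  direction = NA_character_,
                                  run_start = NA_integer_,
                                  run_length = NA_integer_)
      } else {
        truth_rows[[i]] <- tibble(compound_id = ids[i], is_hit = FALSE,
                                  direction = NA_character_,
                                  run_start = NA_integer_,
                                  run_length = NA_integer_)
      }
      if (spec$flux_noise_sd > 0) {
        pct <- pct + rnorm(nt, 0, spec$flux_noise_sd)
      }
      ratio <- vehicle + pct / 100 * span
      flux_rows[[length(flux_rows) + 1]] <-
        tibble(compound_id = ids[i], time_h = times, gfp_rfp_ratio = ratio,
               role = "compound")
    }
    list(flux = dplyr::bind_rows(flux_rows),
         truth = dplyr::bind_rows(truth_rows))
  })
}
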