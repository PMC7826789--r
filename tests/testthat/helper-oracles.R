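# Independent oracles used across the suite. Each is deliberately written
# as the most naive possible implementation (explicit loops, no shared
# code with the package internals).

# Brute-force activity scan: kinases with PoC strictly below the cutoff,
# ordered by ascending PoC then symbol.
oracle_active_profile <- function(poc, cutoff) {
  hits <- character()
  vals <- numeric()
  for (k in names(poc)) {
    v <- poc[[k]]
    if (!is.na(v) && v < cutoff) {
      hits <- c(hits, k)
      vals <- c(vals, v)
    }
  }
  hits[order(vals, hits)]
}

# Brute-force S10 on a named PoC vector (NA cells excluded everywhere).
oracle_s10 <- function(poc, cutoff) {
  n_active <- 0L
  n_assayed <- 0L
  for (v in poc) {
    if (is.na(v)) next
    n_assayed <- n_assayed + 1L
    if (v < cutoff) n_active <- n_active + 1L
  }
  n_active / n_assayed
}

# Brute-force window scan for the flux hit rule: first window of length
# >= min_run where every |pct| > threshold.
oracle_hit_scan <- function(pct, threshold, min_run) {
  n <- length(pct)
  for (start in seq_len(n - min_run + 1)) {
    len <- 0L
    for (i in start:n) {
      if (abs(pct[i]) > threshold) len <- len + 1L else break
    }
    if (len >= min_run) {
      seg <- pct[start:(start + len - 1)]
      return(list(is_hit = TRUE,
                  direction = if (mean(seg) > 0) "induced" else "reduced",
                  run_start = start, run_length = len))
    }
  }
  list(is_hit = FALSE, direction = NA_character_,
       run_start = NA_integer_, run_length = NA_integer_)
}

# Step-by-step greedy re-implementation with explicit nested loops over
# candidates and kinases. Inputs: data frame with compound_id, s10, and a
# list column qualifying_kinases; named character vector bin_of; integer
# depth_target; optional named weights.
oracle_greedy <- function(candidates, bin_of, depth_target, weights = NULL) {
  w <- function(k) {
    if (is.null(weights) || !(k %in% names(weights))) 1 else weights[[k]]
  }
  pool <- candidates$compound_id
  chem <- list()
  bin_n <- list()
  picked <- character()
  repeat {
    if (length(pool) == 0) break
    best_gain <- 0
    gains <- setNames(numeric(length(pool)), pool)
    for (cmp in pool) {
      b <- bin_of[[cmp]]
      g <- 0
      ks <- candidates$qualifying_kinases[[match(cmp, candidates$compound_id)]]
      for (k in ks) {
        have <- if (k %in% names(chem)) chem[[k]] else character()
        if (length(have) < depth_target && !(b %in% have)) g <- g + w(k)
      }
      gains[[cmp]] <- g
    }
    best_gain <- max(gains)
    if (best_gain <= 0 || length(pool) == 0) break
    tied <- names(gains)[gains == best_gain]
    if (length(tied) > 1) {
      ex <- sapply(tied, function(cmp) {
        b <- bin_of[[cmp]]
        if (b %in% names(bin_n)) bin_n[[b]] else 0
      })
      tied <- tied[ex == min(ex)]
    }
    if (length(tied) > 1) {
      s <- candidates$s10[match(tied, candidates$compound_id)]
      tied <- tied[s == min(s)]
    }
    pick <- sort(tied)[1]
    b <- bin_of[[pick]]
    ks <- candidates$qualifying_kinases[[match(pick, candidates$compound_id)]]
    for (k in ks) {
      have <- if (k %in% names(chem)) chem[[k]] else character()
      chem[[k]] <- union(have, b)
    }
    bin_n[[b]] <- (if (b %in% names(bin_n)) bin_n[[b]] else 0) + 1
    picked <- c(picked, pick)
    pool <- setdiff(pool, pick)
  }
  picked
}

# Second-engine substructure oracle: RDKit through the system python.
# Returns a logical matrix [molecules x patterns].
rdkit_substructure_matrix <- function(smiles, smarts) {
  script <- '
import sys, json
from rdkit import Chem
from rdkit import RDLogger
RDLogger.DisableLog("rdApp.*")
inp = json.load(sys.stdin)
out = []
for smi in inp["smiles"]:
    mol = Chem.MolFromSmiles(smi)
    row = []
    for pat in inp["smarts"]:
        row.append(bool(mol.HasSubstructMatch(Chem.MolFromSmarts(pat))))
    out.append(row)
json.dump(out, sys.stdout)
'
  payload <- jsonlite::toJSON(list(smiles = smiles, smarts = smarts))
  res <- system2("python", c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  m <- jsonlite::fromJSON(paste(res, collapse = ""))
  matrix(as.logical(m), nrow = length(smiles), byrow = FALSE)
}

# Random small set-selection instance within the <= 8 candidates x <= 6
# kinases envelope, used by the greedy-equivalence suites.
random_instance <- function(seed) {
  set.seed(seed)
  n_cand <- sample(2:8, 1)
  n_kin <- sample(2:6, 1)
  kin <- paste0("K", seq_len(n_kin))
  bins <- paste0("B", 1:3)
  tibble::tibble(
    compound_id = sprintf("C%02d", seq_len(n_cand)),
    s10 = round(runif(n_cand, 0.001, 0.024), sample(2:4, 1)),
    qualifying_kinases = lapply(seq_len(n_cand), function(i) {
      sort(sample(kin, sample(1:n_kin, 1)))
    }),
    bin = sample(bins, n_cand, replace = TRUE)
  )
}

# Small valid panel used by many tests.
make_panel <- function(kinases, families = NULL) {
  kinase_panel(tibble::tibble(
    kinase = kinases,
    family = families %||% rep_len(c("TK", "CMGC", "AGC", "STE"), length(kinases)),
    is_wild_type = TRUE, is_human = TRUE
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
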