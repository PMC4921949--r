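# Shared fixtures and the independent combining-table oracle.

# The worked-example bundle is deterministic and moderately large; build it
# once per test run.
wx_fixture <- worked_examples()

# ---- independent combining-table oracle ------------------------------------
# Literal row scan: each row of the combining table is written as the minimum
# per-tier counts it requires, and a multiset matches a verdict class when it
# dominates at least one of its rows. Kept deliberately separate from the
# package's boolean-algebra implementation.

oracle_path_rows <- rbind(             # (very_strong, strong, moderate, supporting)
  c(1, 1, 0, 0),
  c(1, 0, 2, 0),
  c(1, 0, 1, 1),
  c(1, 0, 0, 2),
  c(0, 2, 0, 0),
  c(0, 1, 3, 0),
  c(0, 1, 2, 2),
  c(0, 1, 1, 4)
)
oracle_lp_rows <- rbind(
  c(1, 0, 1, 0),
  c(0, 1, 1, 0),
  c(0, 1, 0, 2),
  c(0, 0, 3, 0),
  c(0, 0, 2, 2),
  c(0, 0, 1, 4)
)
oracle_benign_rows <- rbind(           # (standalone, strong, supporting)
  c(1, 0, 0),
  c(0, 2, 0)
)
oracle_lb_rows <- rbind(
  c(0, 1, 1),
  c(0, 0, 2)
)

scan_rows <- function(counts, rows) {
  # counts: matrix with one row per case; rows: table of per-tier minima
  hit <- rep(FALSE, nrow(counts))
  for (r in seq_len(nrow(rows))) {
    dominated <- rep(TRUE, nrow(counts))
    for (j in seq_len(ncol(rows))) {
      dominated <- dominated & counts[, j] >= rows[r, j]
    }
    hit <- hit | dominated
  }
  hit
}

oracle_verdicts <- function(counts7) {
  # counts7: matrix with columns pvs, ps, pm, pp, ba, bs, bp
  p_counts <- counts7[, 1:4, drop = FALSE]
  b_counts <- counts7[, 5:7, drop = FALSE]
  path <- scan_rows(p_counts, oracle_path_rows)
  lp <- scan_rows(p_counts, oracle_lp_rows)
  ben <- scan_rows(b_counts, oracle_benign_rows)
  lb <- scan_rows(b_counts, oracle_lb_rows)
  strong_conflict <- (counts7[, 1] + counts7[, 2] >= 1) &
    (counts7[, 5] + counts7[, 6] >= 1)
  conflict <- strong_conflict | ((path | lp) & (ben | lb))
  out <- rep("VUS", nrow(counts7))
  out[lb] <- "likely_benign"
  out[lp] <- "likely_pathogenic"
  out[ben] <- "benign"
  out[path] <- "pathogenic"
  out[conflict] <- "VUS"
  out
}

all_count_grids <- function(max_per_tier) {
  as.matrix(expand.grid(pvs = 0:max_per_tier, ps = 0:max_per_tier,
                        pm = 0:max_per_tier, pp = 0:max_per_tier,
                        ba = 0:max_per_tier, bs = 0:max_per_tier,
                        bp = 0:max_per_tier))
}

impl_verdicts <- function(counts7) {
  genevalid:::verdict_from_counts(counts7[, 1], counts7[, 2], counts7[, 3],
                                  counts7[, 4], counts7[, 5], counts7[, 6],
                                  counts7[, 7])
}

codes_from_counts <- function(k) {
  rep(c("path_very_strong", "path_strong", "path_moderate", "path_supporting",
        "benign_standalone", "benign_strong", "benign_supporting"), k)
}

verdict_rank <- function(v) {
  match(v, c("benign", "likely_benign", "VUS", "likely_pathogenic",
             "pathogenic"))
}

# ---- small synthetic scaffolds ---------------------------------------------

# One proven gene (via condition C0 with three probands) plus k unrelated
# probands of a second condition C1 carrying the same pathogenic variant.
sweep_bundle <- function(k) {
  features <- list(C0 = c("c0_f1", "c0_f2"), C1 = c("c1_f1", "c1_f2"))
  cases0 <- tibble::tibble(
    variant = "V1", proband = sprintf("P0_%d", 1:3),
    family = sprintf("F0_%d", 1:3), condition = "C0",
    phenotype_features = list(features$C0),
    severity = "classic", onset = "adult", de_novo = "none", zygosity = "het"
  )
  cases1 <- if (k > 0) {
    tibble::tibble(
      variant = "V1", proband = sprintf("P1_%d", seq_len(k)),
      family = sprintf("F1_%d", seq_len(k)), condition = "C1",
      phenotype_features = list(features$C1),
      severity = "classic", onset = "adult", de_novo = "none",
      zygosity = "het"
    )
  } else NULL
  evidence_bundle(
    genes = tibble::tibble(symbol = "GENE1"),
    conditions = tibble::tibble(
      id = c("C0", "C1"), name = c("Condition zero", "Condition one"),
      inheritance = list("AD", "AD"), features = unname(features)
    ),
    variants = tibble::tibble(id = "V1", gene = "GENE1", hgvs = "p.Arg1Cys",
                              consequence = "missense"),
    cases = dplyr::bind_rows(cases0, cases1),
    segregations = tibble::tibble(variant = "V1", family = "FSEG", lod = 3.6,
                                  families = 2L, condition = "C0"),
    functionals = tibble::tibble(variant = "V1", assay = "biochemical",
                                 effect = "loss_of_function",
                                 mechanism_concordant = TRUE)
  )
}

strength_rank <- function(s) match(s, c("none", "suggested", "emerging",
                                        "strong"))
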