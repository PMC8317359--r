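#' Partition a patient registry into eligible and excluded records
#'
#' Records carrying any exclusion flag (prior therapy, tumour volume
#' below 1 cm^3, surgery elsewhere) are excluded; the partition is
#' exhaustive and disjoint.
#'
#' @param records a registry data.frame with a character column
#'   `exclusion_flags` (`""` or `;`-separated flag names), e.g. from
#'   [generate_registry()].
#' @return list with data.frames `eligible` and `excluded`.
#' @export
apply_eligibility <- function(records) {
  stopifnot(is.data.frame(records), "exclusion_flags" %in% names(records))
  flagged <- nzchar(records$exclusion_flags)
  excluded <- records[flagged, , drop = FALSE]
  eligible <- records[!flagged, , drop = FALSE]
  if (nrow(excluded) && "split" %in% names(excluded))
    excluded$split <- "excluded"
  list(eligible = eligible, excluded = excluded)
}

#' Random train/test split of the eligible cohort
#'
#' Assigns `ceiling(ratio * n)` records to the training set (so a 7:3
#' split of 86 patients yields 61/25) by a seeded permutation; the
#' assignment is a bijection, reproducible under the same seed, and no
#' stratification is applied.
#'
#' @param eligible data.frame of eligible records.
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed for the permutation.
#' @return the input data.frame with a `split` column (`"train"` /
#'   `"test"`).
#' @export
split_cohort <- function(eligible, ratio = 0.7, seed = 1L) {
  stopifnot(is.data.frame(eligible))
  n <- nrow(eligible)
  if (n < 2L) stop("need at least 2 eligible records to split")
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("`ratio` must be in (0, 1)")
  n_train <- min(max(ceiling(ratio * n), 1L), n - 1L)
  set.seed(seed)
  perm <- sample.int(n)
  split <- rep("test", n)
  split[perm[seq_len(n_train)]] <- "train"
  eligible$split <- split
  eligible
}

#' Baseline characteristic comparison between training and testing sets
#'
#' Continuous characteristics (age) are compared with the Mann-Whitney U
#' test and categorical characteristics with the Pearson chi-square test
#' without continuity correction.  A characteristic constant in both
#' groups is reported with p = 1 and a note; expected cell counts below
#' 5 add a note rather than switching tests.
#'
#' @param split_df data.frame with a `split` column (`train` / `test`)
#'   plus the characteristic columns.
#' @param continuous names of continuous columns (default `"age"`).
#' @param categorical names of categorical columns; defaults to the
#'   registry columns present in `split_df`.
#' @return data.frame with columns `characteristic`, `test`,
#'   `statistic`, `p_value`, `note`.
#' @export
baseline_table <- function(split_df,
                           continuous = "age",
                           categorical = intersect(
                             c("figo_stage", "grade", "stromal_invasion",
                               "lvsi", "tnc_group", "cox2_group"),
                             names(split_df))) {
  stopifnot("split" %in% names(split_df))
  g <- split_df$split
  stopifnot(all(g %in% c("train", "test")))
  if (!any(g == "train") || !any(g == "test"))
    stop("both split groups must be non-empty")
  rows <- list()
  for (v in intersect(continuous, names(split_df))) {
    x <- split_df[[v]][g == "train"]
    y <- split_df[[v]][g == "test"]
    if (length(unique(c(x, y))) == 1L) {
      rows[[v]] <- data.frame(characteristic = v, test = "Mann-Whitney U",
                              statistic = NA_real_, p_value = 1,
                              note = "constant in both groups")
    } else {
      mw <- mann_whitney(x, y)
      rows[[v]] <- data.frame(characteristic = v, test = "Mann-Whitney U",
                              statistic = mw$u, p_value = mw$p, note = "")
    }
  }
  for (v in categorical) {
    vals <- split_df[[v]]
    if (length(unique(vals)) == 1L) {
      rows[[v]] <- data.frame(characteristic = v,
                              test = "Pearson chi-square",
                              statistic = NA_real_, p_value = 1,
                              note = "constant in both groups")
      next
    }
    tab <- table(g, vals)
    note <- ""
    res <- withCallingHandlers(
      chisq.test(tab, correct = FALSE),
      warning = function(w) {
        note <<- "expected count < 5"
        invokeRestart("muffleWarning")
      })
    rows[[v]] <- data.frame(characteristic = v,
                            test = "Pearson chi-square",
                            statistic = unname(res$statistic),
                            p_value = unname(res$p.value), note = note)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
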