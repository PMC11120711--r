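PATTERN_LEVELS <- c("complex_tubular", "mucinous", "solid")
MUTATION_LEVELS <- c("KRAS", "NRAS", "BRAF", "wt")

#' Cohort specification
#'
#' Counts and stiffness distributions defining the simulated study cohort:
#' 46 clinical cases (33 low-grade, 13 high-grade) contributing 54 regions of
#' interest (ROIs) of a single morphological pattern each (34 complex
#' tubular, 6 mucinous, 14 solid). Per-ROI mean stiffness is drawn from the
#' mutation-group normal distributions (mutant 967 +/- 145 kPa, wild type
#' 751 +/- 92 kPa) truncated at the 520 kPa tumor-cell floor.
#'
#' @param n_cases Number of clinical cases.
#' @param roi_counts_by_pattern Named list `pattern -> c(mutant, wildtype)`
#'   ROI counts.
#' @param gene_split Named vector of mutant ROI counts by gene.
#' @param stiffness_params Named list `group -> c(mean, sd)` in kPa; groups
#'   `mutant` and `wildtype`, plus optional per-pattern overrides
#'   `complex_tubular`, `mucinous`, `solid` used when
#'   `sample_cohort(..., by_pattern = TRUE)`.
#' @param msi_counts Named vector of MSI ROI counts by pattern.
#' @param floor_kpa Truncation floor for sampled stiffness, kPa.
#' @return An object of class `oce_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 46L,
                        roi_counts_by_pattern = list(
                          complex_tubular = c(mutant = 11L, wildtype = 23L),
                          mucinous = c(mutant = 3L, wildtype = 3L),
                          solid = c(mutant = 10L, wildtype = 4L)),
                        gene_split = c(KRAS = 20L, NRAS = 1L, BRAF = 3L),
                        stiffness_params = list(
                          mutant = c(mean = 967, sd = 145),
                          wildtype = c(mean = 751, sd = 92),
                          complex_tubular = c(mean = 770, sd = 164),
                          mucinous = c(mean = 968, sd = 234),
                          solid = c(mean = 1039, sd = 270)),
                        msi_counts = c(complex_tubular = 1L, solid = 3L),
                        floor_kpa = 520) {
  cnt <- vapply(roi_counts_by_pattern, sum, numeric(1))
  n_mut <- sum(vapply(roi_counts_by_pattern, `[`, numeric(1), "mutant"))
  if (sum(gene_split) != n_mut)
    stop("gene_split must sum to the total mutant ROI count", call. = FALSE)
  if (any(cnt < 0) || floor_kpa <= 0)
    stop("invalid cohort counts or floor", call. = FALSE)
  for (p in names(stiffness_params)) {
    par <- stiffness_params[[p]]
    if (par[["mean"]] <= 0 || par[["sd"]] < 0)
      stop("stiffness means must be positive and sds nonnegative",
           call. = FALSE)
  }
  structure(list(n_cases = n_cases,
                 roi_counts_by_pattern = roi_counts_by_pattern,
                 gene_split = gene_split,
                 stiffness_params = stiffness_params,
                 msi_counts = msi_counts,
                 floor_kpa = floor_kpa),
            class = "oce_cohort_spec")
}

# Fixed case/ROI layout reproducing every cohort margin exactly:
#  - 46 cases: 13 high-grade (10 mutant: 9 KRAS + 1 BRAF), 33 low-grade
#    (10 mutant: 7 KRAS + 1 NRAS + 2 BRAF)
#  - 54 ROIs via 8 dual-pattern cases: 4 tubular+solid both-KRAS (high grade),
#    case 21 tubular-KRAS + mucinous-wt (the discordant heterogeneous case),
#    2 tubular+mucinous wt, 1 tubular+solid wt
#  - ROI genes: KRAS 20, NRAS 1, BRAF 3; case genes: KRAS 16, NRAS 1, BRAF 3
#  - MSI: 3 high-grade cases, 4 ROIs (1 tubular + 3 solid)
table1_layout <- function() {
  row <- function(case_id, grade, pattern, mutation, msi)
    data.frame(case_id = case_id, grade = grade, pattern = pattern,
               mutation = mutation, msi = msi, stringsAsFactors = FALSE)
  out <- list()
  # high-grade dual both-KRAS cases (case 1 carries both MSI ROIs)
  for (cid in 1:4) {
    msi <- if (cid == 1) "MSI" else "MSS"
    out[[length(out) + 1]] <- row(cid, "high", "complex_tubular", "KRAS", msi)
    out[[length(out) + 1]] <- row(cid, "high", "solid", "KRAS", msi)
  }
  # high-grade single solid cases
  for (cid in 5:9)
    out[[length(out) + 1]] <- row(cid, "high", "solid", "KRAS",
                                  if (cid %in% 5:6) "MSI" else "MSS")
  out[[length(out) + 1]] <- row(10, "high", "solid", "BRAF", "MSS")
  for (cid in 11:13)
    out[[length(out) + 1]] <- row(cid, "high", "solid", "wt", "MSS")
  # low-grade single mutant cases
  for (cid in 14:16)
    out[[length(out) + 1]] <- row(cid, "low", "complex_tubular", "KRAS", "MSS")
  for (cid in 17:19)
    out[[length(out) + 1]] <- row(cid, "low", "mucinous", "KRAS", "MSS")
  out[[length(out) + 1]] <- row(20, "low", "complex_tubular", "NRAS", "MSS")
  # case 21: intratumoral heterogeneity, discordant KRAS status
  out[[length(out) + 1]] <- row(21, "low", "complex_tubular", "KRAS", "MSS")
  out[[length(out) + 1]] <- row(21, "low", "mucinous", "wt", "MSS")
  for (cid in 22:23)
    out[[length(out) + 1]] <- row(cid, "low", "complex_tubular", "BRAF", "MSS")
  # low-grade dual wild-type cases
  for (cid in 24:25) {
    out[[length(out) + 1]] <- row(cid, "low", "complex_tubular", "wt", "MSS")
    out[[length(out) + 1]] <- row(cid, "low", "mucinous", "wt", "MSS")
  }
  out[[length(out) + 1]] <- row(26, "low", "complex_tubular", "wt", "MSS")
  out[[length(out) + 1]] <- row(26, "low", "solid", "wt", "MSS")
  # low-grade single tubular wild-type cases
  for (cid in 27:46)
    out[[length(out) + 1]] <- row(cid, "low", "complex_tubular", "wt", "MSS")
  df <- do.call(rbind, out)
  df <- df[order(df$case_id, df$pattern), ]
  df$roi_id <- stats::ave(df$case_id, df$case_id,
                          FUN = function(x) seq_along(x))
  df$roi_id <- sprintf("%02d-%d", df$case_id, df$roi_id)
  rownames(df) <- NULL
  df[, c("case_id", "roi_id", "grade", "pattern", "mutation", "msi")]
}

# truncated-normal sampling by rejection at the floor
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= floor)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Sample a synthetic study cohort
#'
#' Builds the fixed case/ROI layout (all pattern, grade, mutation and MSI
#' counts are assigned, not sampled, so every cohort reproduces the study
#' margins exactly) and draws each ROI's mean stiffness from its group's
#' truncated normal distribution. One designated case (id 21) carries two
#' ROIs of different patterns with discordant KRAS status.
#'
#' @param spec An [cohort_spec()] object.
#' @param seed Integer seed.
#' @param by_pattern If `TRUE`, draw stiffness from the per-pattern
#'   distributions instead of the mutation-group distributions.
#' @return A `data.frame` of class `oce_cohort` with columns `case_id`,
#'   `roi_id`, `grade`, `pattern`, `stiffness_kpa`, `mutation`, `msi`; the
#'   seed is attached as attribute `seed`.
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = 1L, by_pattern = FALSE) {
  df <- table1_layout()
  # validate the layout against the spec counts
  for (p in names(spec$roi_counts_by_pattern)) {
    want <- spec$roi_counts_by_pattern[[p]]
    got_mut <- sum(df$pattern == p & df$mutation != "wt")
    got_wt <- sum(df$pattern == p & df$mutation == "wt")
    if (got_mut != want[["mutant"]] || got_wt != want[["wildtype"]])
      stop("cohort layout does not satisfy the requested counts for ", p,
           call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- nrow(df)
  df$stiffness_kpa <- NA_real_
  if (by_pattern) {
    for (p in PATTERN_LEVELS) {
      par <- spec$stiffness_params[[p]]
      idx <- df$pattern == p
      df$stiffness_kpa[idx] <- rtruncnorm_floor(sum(idx), par[["mean"]],
                                                par[["sd"]], spec$floor_kpa)
    }
  } else {
    for (g in c("mutant", "wildtype")) {
      par <- spec$stiffness_params[[g]]
      idx <- if (g == "mutant") df$mutation != "wt" else df$mutation == "wt"
      df$stiffness_kpa[idx] <- rtruncnorm_floor(sum(idx), par[["mean"]],
                                                par[["sd"]], spec$floor_kpa)
    }
  }
  df <- df[, c("case_id", "roi_id", "grade", "pattern", "stiffness_kpa",
               "mutation", "msi")]
  attr(df, "seed") <- as.integer(seed)
  class(df) <- c("oce_cohort", "data.frame")
  df
}

#' Collapse a ROI cohort to the case level
#'
#' A case is mutant if any of its ROIs carries a driver mutation (the mutated
#' gene is then unique within the case by construction), and MSI if any ROI
#' is MSI.
#'
#' @param cohort An [sample_cohort()] table.
#' @return A `data.frame` with one row per case: `case_id`, `grade`,
#'   `mutation`, `msi`, `n_roi`.
#' @export
cohort_case_table <- function(cohort) {
  sp <- split(cohort, cohort$case_id)
  out <- lapply(sp, function(d) {
    genes <- setdiff(unique(d$mutation), "wt")
    data.frame(case_id = d$case_id[1], grade = d$grade[1],
               mutation = if (length(genes)) genes[1] else "wt",
               msi = if (any(d$msi == "MSI")) "MSI" else "MSS",
               n_roi = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$case_id), ]
}

#' 2x2 mutation-frequency contingency tables
#'
#' `grade_mutation_table` cross-tabulates clinical cases (rows high/low
#' grade) against driver-mutation status; `pattern_mutation_table`
#' cross-tabulates ROIs of two morphological patterns against mutation
#' status. Columns are (mutant, wild type).
#'
#' @param cohort An [sample_cohort()] table.
#' @param pattern_a,pattern_b Patterns for the two rows.
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
grade_mutation_table <- function(cohort) {
  cases <- cohort_case_table(cohort)
  m <- rbind(high = c(sum(cases$grade == "high" & cases$mutation != "wt"),
                      sum(cases$grade == "high" & cases$mutation == "wt")),
             low = c(sum(cases$grade == "low" & cases$mutation != "wt"),
                     sum(cases$grade == "low" & cases$mutation == "wt")))
  colnames(m) <- c("mutant", "wildtype")
  m
}

#' @rdname grade_mutation_table
#' @export
pattern_mutation_table <- function(cohort, pattern_a = "solid",
                                   pattern_b = "complex_tubular") {
  row_for <- function(p) c(sum(cohort$pattern == p & cohort$mutation != "wt"),
                           sum(cohort$pattern == p & cohort$mutation == "wt"))
  m <- rbind(row_for(pattern_a), row_for(pattern_b))
  dimnames(m) <- list(c(pattern_a, pattern_b), c("mutant", "wildtype"))
  m
}

#' Read and write cohort CSV files
#'
#' The cohort schema is `case_id, roi_id, grade, pattern, stiffness_kpa,
#' mutation, msi`. On reading, pattern/mutation/MSI labels are normalized to
#' their canonical spelling (with a warning for case variants); rows with
#' non-positive or missing stiffness are rejected with their line numbers;
#' unknown columns are preserved.
#'
#' @param path File path.
#' @param cohort An `oce_cohort` table.
#' @return `read_cohort_csv` returns an `oce_cohort` data.frame;
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "roi_id", "pattern", "stiffness_kpa", "mutation", "msi")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("cohort CSV lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  norm <- function(x, levels, field) {
    canon <- levels[match(tolower(gsub("[ -]", "_", x)), tolower(levels))]
    bad <- is.na(canon)
    if (any(canon[!bad] != x[!bad]))
      warning("normalized case-variant ", field, " labels", call. = FALSE)
    if (any(bad))
      stop("unknown ", field, " labels at rows: ",
           paste(which(bad), collapse = ", "), call. = FALSE)
    canon
  }
  df$pattern <- norm(df$pattern, PATTERN_LEVELS, "pattern")
  df$mutation <- norm(df$mutation, MUTATION_LEVELS, "mutation")
  df$msi <- norm(df$msi, c("MSI", "MSS"), "msi")
  bad <- !is.finite(df$stiffness_kpa) | df$stiffness_kpa <= 0
  if (any(bad)) {
    warning("rejected rows with invalid stiffness: ",
            paste(which(bad), collapse = ", "), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("oce_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
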