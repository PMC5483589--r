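#' Read an expression matrix from TSV
#'
#' Rows are probes or genes, columns are patients; the first column holds
#' row ids and the header holds patient ids. Missing values are rejected:
#' the clustering chain assumes a complete matrix.
#'
#' @param path path to the TSV file.
#' @param row_kind `"gene"` or `"probe"`.
#' @return Numeric matrix with an attribute `row_kind`.
#' @export
read_expression_matrix <- function(path, row_kind = c("gene", "probe")) {
  row_kind <- match.arg(row_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- if (row_kind == "gene") canonical_symbol(d[[1L]]) else
    as.character(d[[1L]])
  expression_matrix(m, row_kind = row_kind)
}

#' Validate an expression matrix
#' @param m numeric matrix, rows = probes/genes, columns = patients.
#' @param row_kind `"gene"` or `"probe"`.
#' @return The matrix with attribute `row_kind`.
#' @export
expression_matrix <- function(m, row_kind = c("gene", "probe")) {
  row_kind <- match.arg(row_kind)
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix needs row and column names")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate row ids")
  if (anyDuplicated(colnames(m))) stop("duplicate patient ids")
  if (anyNA(m)) stop("missing expression values are not accepted")
  attr(m, "row_kind") <- row_kind
  m
}

#' Write an expression matrix to TSV
#' @param m expression matrix.
#' @param path output path.
#' @param id_column header name of the row-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "id") {
  d <- data.frame(rownames(m), m, check.names = FALSE)
  names(d)[1L] <- id_column
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival annotations
#'
#' TSV with header `patient`, `time`, `event` and optionally `subtype`.
#' Times are in years unless `unit = "months"`, in which case they are
#' divided by 12 on ingest.
#'
#' @param path path to the TSV file.
#' @param unit `"years"` (default) or `"months"`.
#' @return data.frame `patient`, `time`, `event`, `subtype`.
#' @export
read_survival_table <- function(path, unit = c("years", "months")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("patient", "time", "event") %in% names(d))) {
    stop("survival table needs columns patient, time, event")
  }
  if (!"subtype" %in% names(d)) d$subtype <- "unknown"
  if (unit == "months") d$time <- d$time / 12
  survival_records(d)
}

survival_records <- function(d) {
  if (any(d$time < 0)) stop("negative survival time")
  if (!all(d$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (anyDuplicated(d$patient)) stop("duplicate patient ids")
  d$patient <- as.character(d$patient)
  d
}

#' Read a probe-to-gene map
#' @param path TSV with header `probe`, `gene`; each probe at most once.
#' @return Named character vector probe -> gene symbol.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("probe", "gene") %in% names(d))) {
    stop("probe map needs columns probe, gene")
  }
  if (anyDuplicated(d$probe)) stop("probe mapped more than once")
  stats::setNames(canonical_symbol(d$gene), as.character(d$probe))
}

#' Collapse probe-level expression to gene level
#'
#' For each gene the single probe with the highest mean expression across
#' all patients represents the gene; ties go to the lexicographically
#' smallest probe id. Unmapped probes are dropped (count reported as an
#' attribute).
#'
#' @param expr probe-level expression matrix.
#' @param map named character vector probe -> gene.
#' @return Gene-level expression matrix with attributes `n_dropped`
#'   (unmapped probes) and `chosen_probe` (gene -> representative probe).
#' @export
collapse_probes <- function(expr, map) {
  expr <- expression_matrix(expr, row_kind = attr(expr, "row_kind") %||% "probe")
  mapped <- intersect(rownames(expr), names(map))
  if (length(mapped) == 0L) stop("no probe maps to a gene")
  n_dropped <- nrow(expr) - length(mapped)
  means <- rowMeans(expr[mapped, , drop = FALSE])
  ord <- order(map[mapped], -means, mapped)  # per gene: max mean, then lex id
  mapped <- mapped[ord]
  first <- !duplicated(map[mapped])
  chosen <- mapped[first]
  out <- expr[chosen, , drop = FALSE]
  rownames(out) <- unname(map[chosen])
  out <- out[order(rownames(out)), , drop = FALSE]
  out <- expression_matrix(out, row_kind = "gene")
  attr(out, "n_dropped") <- n_dropped
  attr(out, "chosen_probe") <- stats::setNames(chosen, map[chosen])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantile-normalize an expression matrix across patients
#'
#' Each column's sorted values are replaced by the across-column mean of
#' sorted values at each rank (limma's implementation; ties within a
#' column receive the average of their target values). Column rank orders
#' are preserved.
#'
#' @param expr expression matrix with >= 2 columns; a single column is
#'   returned unchanged with a warning.
#' @return Normalized expression matrix.
#' @export
quantile_normalize <- function(expr) {
  kind <- attr(expr, "row_kind") %||% "gene"
  expr <- expression_matrix(expr, row_kind = kind)
  if (ncol(expr) < 2L) {
    warning("single-column matrix: quantile normalization is the identity")
    return(expr)
  }
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  expression_matrix(out, row_kind = kind)
}

#' Restrict an expression matrix to a gene signature
#'
#' @param expr gene-level expression matrix.
#' @param signature character vector of signature genes.
#' @return Row-subset matrix with attributes `n_mapped` and `unmapped`
#'   (signature genes absent from the matrix).
#' @export
signature_matrix <- function(expr, signature) {
  signature <- unique(canonical_symbol(signature))
  mapped <- intersect(signature, rownames(expr))
  if (length(mapped) < 2L) {
    stop("fewer than 2 signature genes present in the expression matrix")
  }
  out <- expr[sort(mapped), , drop = FALSE]
  out <- expression_matrix(out, row_kind = "gene")
  attr(out, "n_mapped") <- length(mapped)
  attr(out, "unmapped") <- sort(setdiff(signature, mapped))
  out
}

#' Pearson-correlation distance between patients
#'
#' d(i, j) = 1 - r(i, j), where r is the Pearson correlation of the two
#' patients' signature-gene profiles; values lie in \[0, 2\].
#'
#' @param expr expression matrix (rows = signature genes, >= 3).
#' @return Symmetric patient-by-patient distance matrix with zero diagonal.
#' @export
pearson_distance <- function(expr) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) < 3L) stop("need at least 3 genes for correlation distance")
  v <- apply(expr, 2L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance expression profile for patient(s): ",
         paste(colnames(expr)[v == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(expr)
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering in which the distance between clusters is the
#' maximum pairwise member distance; merges happen in non-decreasing height
#' order.
#'
#' @param dist_mat symmetric distance matrix.
#' @return An [stats::hclust] dendrogram.
#' @export
hclust_complete <- function(dist_mat) {
  stopifnot(is.matrix(dist_mat))
  if (nrow(dist_mat) != ncol(dist_mat) ||
      !isTRUE(all.equal(dist_mat, t(dist_mat), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric")
  }
  if (nrow(dist_mat) < 2L) stop("need at least 2 observations")
  stats::hclust(stats::as.dist(dist_mat), method = "complete")
}

#' Dynamic hybrid dendrogram cut
#'
#' Two-stage cluster detection driven only by a minimum cluster size
#' expressed as a fraction of the cohort. Stage 1 reads the cluster count
#' off the dendrogram shape: with merge heights sorted in decreasing order
#' H1 >= H2 >= ..., the widest gap H_t - H_(t+1) within the admissible top
#' region (t at most n / size-floor merges) marks the boundary between
#' between-cluster and within-cluster merges, and the tree is cut just
#' below H_t, yielding t + 1 branches. Every branch meeting the size floor
#' `max(2, floor(min_fraction * n))` becomes a cluster seed; stage 2
#' assigns each remaining observation to the seed with the smallest mean
#' dissimilarity. If fewer than two seeds emerge, or the considered merge
#' heights are all equal (no shape information, e.g. equidistant points),
#' everything collapses into a single cluster. Fully deterministic: ties
#' in the widest gap resolve to the highest cut (fewest clusters).
#'
#' @param dend an [stats::hclust] object.
#' @param dist_mat the distance matrix the dendrogram was built from.
#' @param min_fraction minimum cluster size as a fraction of n, in
#'   (0, 0.5].
#' @return Integer vector of cluster labels (1..k, contiguous, ordered by
#'   first appearance), named by observation.
#' @export
dynamic_hybrid_cut <- function(dend, dist_mat, min_fraction = 0.125) {
  stopifnot(inherits(dend, "hclust"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 0.5) {
    stop("min_fraction must lie in (0, 0.5]")
  }
  n <- length(dend$order)
  floor_size <- max(2L, floor(min_fraction * n))
  obs <- dend$labels %||% as.character(seq_len(n))
  H <- sort(dend$height, decreasing = TRUE)
  t_max <- min(length(H) - 1L, max(1L, floor(n / floor_size)))
  if (t_max < 1L || n < 2L * floor_size) {
    return(stats::setNames(rep(1L, n), obs))
  }
  gaps <- H[seq_len(t_max)] - H[seq_len(t_max) + 1L]
  if (max(gaps) <= 0) {
    return(stats::setNames(rep(1L, n), obs))
  }
  t_star <- which.max(gaps)  # ties -> smallest t -> highest cut
  labs0 <- stats::cutree(dend, k = t_star + 1L)
  sizes <- table(labs0)
  seeds <- as.integer(names(sizes)[sizes >= floor_size])
  if (length(seeds) <= 1L) {
    return(stats::setNames(rep(1L, n), obs))
  }
  lab <- ifelse(labs0 %in% seeds, match(labs0, seeds), NA_integer_)
  unassigned <- which(is.na(lab))
  for (i in unassigned) {
    avg <- vapply(seq_along(seeds), function(k) {
      mean(dist_mat[i, which(lab == k & seq_len(n) != i)])
    }, numeric(1))
    lab[i] <- which.min(avg)  # ties -> smallest seed label
  }
  # relabel contiguously by first appearance
  lab <- match(lab, unique(lab))
  stats::setNames(as.integer(lab), obs)
}

#' Kaplan-Meier curve (product-limit estimator)
#'
#' Standard convention: subjects censored exactly at an event time remain
#' in that risk set.
#'
#' @param records data.frame with `time` (years, >= 0) and `event` (0/1).
#' @param horizon display truncation in years (default 15); estimation
#'   always uses the full follow-up.
#' @return List of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`
#'   over all observed times, plus `horizon`.
#' @export
km_curve <- function(records, horizon = 15) {
  records <- survival_records(records_with_patient(records))
  if (nrow(records) < 1L) stop("need at least one subject")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, horizon = horizon),
            class = "km_curve")
}

records_with_patient <- function(records) {
  if (!"patient" %in% names(records)) {
    records$patient <- paste0("P", seq_len(nrow(records)))
  }
  if (!"subtype" %in% names(records)) records$subtype <- "unknown"
  records
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function lookup; S(0) = 1 and S(t) = 1 before the
#' first event. `km_survival_at(curve, 5)` is the 5-year
#' metastasis-free-survival rate.
#'
#' @param curve a `km_curve`.
#' @param t non-negative time (years).
#' @return Survival probability S(t).
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  idx <- which(curve$time <= t)
  if (length(idx) == 0L) return(1)
  curve$surv[max(idx)]
}

#' k-sample log-rank test
#'
#' Unweighted log-rank chi-square with k - 1 degrees of freedom comparing
#' survival between patient groups; no continuity correction. The full
#' follow-up is used (any display horizon affects plotting only).
#'
#' @param records data.frame with `patient`, `time`, `event`.
#' @param groups named vector (patient -> cluster label) or a vector
#'   aligned with `records` rows.
#' @return List of class `logrank_result`: `chi_square`, `df`, `pvalue`,
#'   `n_groups`.
#' @export
logrank_test <- function(records, groups) {
  records <- survival_records(records_with_patient(records))
  if (!is.null(names(groups))) {
    if (!all(records$patient %in% names(groups))) {
      stop("every patient needs a group label")
    }
    g <- groups[records$patient]
  } else {
    if (length(groups) != nrow(records)) {
      stop("group vector must match the records")
    }
    g <- groups
  }
  g <- factor(g)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  if (sum(records$event) == 0L) stop("no events observed")
  records$.group <- g
  sd <- survival::survdiff(survival::Surv(time, event) ~ .group,
                           data = records, rho = 0)
  df <- nlevels(g) - 1L
  chisq <- unname(sd$chisq)
  structure(list(chi_square = chisq, df = df,
                 pvalue = stats::pchisq(chisq, df, lower.tail = FALSE),
                 n_groups = nlevels(g)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4g on %d df, p = %.4g (%d groups)\n",
              x$chi_square, x$df, x$pvalue, x$n_groups))
  invisible(x)
}

#' Stratify a cohort by a gene signature and test survival differences
#'
#' The full chain: optional probe-to-gene collapse, quantile normalization
#' across patients, restriction to the signature genes, Pearson-correlation
#' distance, complete-linkage clustering, dynamic hybrid cut, and (when
#' more than one cluster is detected) a log-rank comparison of
#' metastasis-free survival with per-cluster Kaplan-Meier curves, 5-year
#' MFS rates and subtype composition. With `subtype_filter` the cohort is
#' first restricted to one molecular subtype and the default minimum
#' cluster fraction switches from 0.125 to 0.25.
#'
#' @param expr expression matrix (gene- or probe-level).
#' @param survival_data data.frame `patient`, `time`, `event`, optional
#'   `subtype`.
#' @param signature character vector of signature genes.
#' @param probe_map optional probe -> gene map for probe-level matrices.
#' @param min_fraction minimum cluster fraction; default 0.125, or 0.25
#'   under `subtype_filter`.
#' @param subtype_filter optional subtype label to restrict to.
#' @param normalize quantile-normalize before clustering (default TRUE).
#' @return List of class `stratification`: `assignment`, `k`, `logrank`
#'   (`NULL` if k = 1), `km` (per-cluster `km_curve`s), `mfs5` (per-cluster
#'   S(5)), `subtype_composition`, `n_mapped`/`unmapped` signature
#'   accounting, `n_patients`, `min_fraction`.
#' @export
stratify <- function(expr, survival_data, signature, probe_map = NULL,
                     min_fraction = NULL, subtype_filter = NULL,
                     normalize = TRUE) {
  survival_data <- survival_records(records_with_patient(survival_data))
  if (!is.null(subtype_filter)) {
    if (!subtype_filter %in% survival_data$subtype) {
      stop("subtype label not present in annotations: ", subtype_filter)
    }
    survival_data <- survival_data[survival_data$subtype == subtype_filter, ,
                                   drop = FALSE]
  }
  if (is.null(min_fraction)) {
    min_fraction <- if (is.null(subtype_filter)) 0.125 else 0.25
  }
  if (!is.null(probe_map)) expr <- collapse_probes(expr, probe_map)
  patients <- intersect(colnames(expr), survival_data$patient)
  if (length(patients) < 4L) {
    stop("fewer than 4 patients shared between expression and survival data")
  }
  expr <- expr[, patients, drop = FALSE]
  expr <- expression_matrix(expr, row_kind = "gene")
  survival_data <-
    survival_data[match(patients, survival_data$patient), , drop = FALSE]
  if (normalize && ncol(expr) >= 2L) expr <- quantile_normalize(expr)
  sig <- signature_matrix(expr, signature)
  d <- pearson_distance(sig)
  dend <- hclust_complete(d)
  assignment <- dynamic_hybrid_cut(dend, d, min_fraction)
  names(assignment) <- patients
  k <- length(unique(assignment))
  lr <- NULL
  if (k >= 2L) lr <- logrank_test(survival_data, assignment)
  km <- lapply(sort(unique(assignment)), function(cl) {
    km_curve(survival_data[assignment == cl, , drop = FALSE])
  })
  names(km) <- paste0("cluster", sort(unique(assignment)))
  mfs5 <- vapply(km, km_survival_at, numeric(1), t = 5)
  comp <- table(cluster = assignment, subtype = survival_data$subtype)
  structure(list(assignment = assignment, k = k, logrank = lr, km = km,
                 mfs5 = mfs5, subtype_composition = comp,
                 n_mapped = attr(sig, "n_mapped"),
                 unmapped = attr(sig, "unmapped"),
                 n_patients = length(patients),
                 min_fraction = min_fraction),
            class = "stratification")
}

#' @export
print.stratification <- function(x, ...) {
  cat(sprintf(
    "stratification: %d patients, %d signature genes mapped, k = %d cluster(s)\n",
    x$n_patients, x$n_mapped, x$k))
  if (!is.null(x$logrank)) print(x$logrank) else
    cat("  single cluster: log-rank test not applicable\n")
  cat("  5-year MFS per cluster:",
      paste(sprintf("%s=%.3f", names(x$mfs5), x$mfs5), collapse = ", "), "\n")
  invisible(x)
}
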