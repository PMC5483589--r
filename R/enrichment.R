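#' Read a differential-expression result table
#'
#' TSV with header `gene log2fc pvalue fdr`; gene symbols are uppercased
#' and must be unique within a table.
#'
#' @param path path to the TSV file.
#' @param comparison_label label for the comparison; defaults to file name.
#' @return data.frame of class `deg_table` with attribute
#'   `comparison_label`.
#' @export
read_deg_table <- function(path, comparison_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  deg_table(d, comparison_label)
}

#' Validate a differential-expression table
#'
#' @param d data.frame with columns `gene`, `log2fc`, `pvalue`, `fdr`.
#' @param comparison_label label for the comparison.
#' @return The validated data.frame, class `deg_table`.
#' @export
deg_table <- function(d, comparison_label = "comparison") {
  need <- c("gene", "log2fc", "pvalue", "fdr")
  if (!all(need %in% names(d))) {
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  }
  d$gene <- canonical_symbol(d$gene)
  if (anyDuplicated(d$gene)) {
    stop("duplicate gene(s) in DEG table: ",
         paste(unique(d$gene[duplicated(d$gene)]), collapse = ", "))
  }
  if (any(d$pvalue < 0 | d$pvalue > 1) || any(d$fdr < 0 | d$fdr > 1)) {
    stop("p-values and FDR values must lie in [0, 1]")
  }
  rownames(d) <- NULL
  structure(d, class = c("deg_table", "data.frame"),
            comparison_label = comparison_label)
}

#' Write a DEG table to TSV
#' @param d a `deg_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(d, path) {
  utils::write.table(d[, c("gene", "log2fc", "pvalue", "fdr")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

significant_genes <- function(d, threshold = 0.05) {
  d$gene[d$fdr < threshold]
}

#' Stable targets: intersection of significant genes across DEG tables
#'
#' Genes significant (FDR below `threshold`) in every table are the stable
#' perturbation targets. The consensus log2 fold-change is taken from the
#' first table; genes whose fold-change sign differs between tables are
#' flagged discordant and excluded with a warning.
#'
#' @param tables list of >= 2 `deg_table` objects.
#' @param threshold FDR significance cutoff (default 0.05).
#' @return data.frame `gene`, `log2fc` (consensus), sorted by gene, with
#'   attribute `discordant` listing excluded genes.
#' @export
common_targets <- function(tables, threshold = 0.05) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop("need at least two DEG tables")
  }
  for (d in tables) {
    if (!all(c("gene", "fdr", "log2fc") %in% names(d)) || nrow(d) == 0L) {
      stop("each element must be a non-empty DEG table")
    }
  }
  sig_sets <- lapply(tables, significant_genes, threshold = threshold)
  common <- Reduce(intersect, sig_sets)
  if (length(common) == 0L) {
    out <- data.frame(gene = character(), log2fc = numeric())
    attr(out, "discordant") <- character()
    return(out)
  }
  signs <- sapply(tables, function(d) {
    sign(d$log2fc[match(common, d$gene)])
  })
  signs <- matrix(signs, nrow = length(common))
  concordant <- apply(signs, 1L, function(s) length(unique(s)) == 1L)
  discordant <- common[!concordant]
  if (length(discordant) > 0L) {
    warning(length(discordant), " gene(s) excluded for discordant ",
            "fold-change sign: ", paste(sort(discordant), collapse = ", "))
  }
  common <- sort(common[concordant])
  first <- tables[[1L]]
  out <- data.frame(gene = common,
                    log2fc = first$log2fc[match(common, first$gene)])
  attr(out, "discordant") <- sort(discordant)
  out
}

#' Split targets into all / up / down lists by fold-change sign
#'
#' @param targets data.frame with `gene` and `log2fc` (e.g. from
#'   [common_targets()]).
#' @return List of class `target_lists` with character vectors `all`, `up`
#'   (log2fc > 0) and `down` (log2fc < 0); genes with log2fc exactly 0 stay
#'   in `all` only.
#' @export
split_targets <- function(targets) {
  stopifnot(is.data.frame(targets),
            all(c("gene", "log2fc") %in% names(targets)))
  if (any(is.na(targets$log2fc))) stop("every gene needs a fold-change")
  g <- canonical_symbol(targets$gene)
  structure(list(all = sort(g),
                 up = sort(g[targets$log2fc > 0]),
                 down = sort(g[targets$log2fc < 0])),
            class = "target_lists")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: tab-separated `name`, `description`, then members. Set
#' names must be unique; members are uppercased and deduplicated.
#'
#' @param path path to the GMT file.
#' @return Named list of class `gene_set_collection`; each element is a
#'   character vector of members with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    bad <- which(lengths(parts) < 3L)[1L]
    stop(sprintf("malformed GMT line %d: need name, description, >=1 member",
                 bad))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(parts, function(p) {
    members <- unique(canonical_symbol(p[-(1:2)]))
    attr(members, "description") <- p[2L]
    members
  })
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#' @param collection a `gene_set_collection` (named list of member vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    members <- collection[[nm]]
    desc <- attr(members, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, members), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Over-representation test by hypergeometric tail (Fisher's exact test)
#'
#' One-sided test that the gene list overlaps the gene set more than
#' expected under random draws from the universe:
#' p = P(X >= k) with X ~ Hypergeometric(|universe|, |set n universe|,
#' |list|). The gene set is intersected with the universe before testing.
#'
#' @param list_genes character vector, a subset of `universe`.
#' @param gene_set character vector of set members.
#' @param universe character vector of all measurable genes.
#' @return One-row data.frame: `pvalue`, `overlap_count`, `set_size`
#'   (within universe), `list_size`, `universe_size`.
#' @export
fisher_ora <- function(list_genes, gene_set, universe) {
  universe <- unique(canonical_symbol(universe))
  if (length(universe) == 0L) stop("empty universe")
  list_genes <- unique(canonical_symbol(list_genes))
  if (length(list_genes) == 0L) stop("empty gene list")
  if (!all(list_genes %in% universe)) {
    stop("gene list must be a subset of the universe")
  }
  gene_set <- intersect(unique(canonical_symbol(gene_set)), universe)
  k <- length(intersect(list_genes, gene_set))
  p <- stats::phyper(k - 1L, length(gene_set),
                     length(universe) - length(gene_set),
                     length(list_genes), lower.tail = FALSE)
  data.frame(pvalue = p, overlap_count = k, set_size = length(gene_set),
             list_size = length(list_genes),
             universe_size = length(universe))
}

#' Rank-based enrichment of a gene set by Wilcoxon rank-sum test
#'
#' Compares the differential-expression p-values of in-set genes against
#' out-of-set genes; the one-sided alternative is that in-set genes have
#' smaller p-values (stronger differential signal). The exact null
#' distribution is used when both groups have at most 25 genes and there
#' are no ties, otherwise the normal approximation with tie correction.
#'
#' @param pvalues named numeric vector, gene -> differential p-value.
#' @param gene_set character vector of set members.
#' @param alternative `"less"` (default: in-set p-values smaller) or
#'   `"greater"`.
#' @return The one-sided p-value.
#' @export
wilcoxon_rank_enrichment <- function(pvalues, gene_set,
                                     alternative = c("less", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(names(pvalues))) stop("pvalues must be named by gene")
  genes <- canonical_symbol(names(pvalues))
  gene_set <- unique(canonical_symbol(gene_set))
  inside <- pvalues[genes %in% gene_set]
  outside <- pvalues[!(genes %in% gene_set)]
  if (length(inside) == 0L || length(outside) == 0L) {
    stop("need at least one scored gene inside and outside the set")
  }
  exact <- length(inside) <= 25L && length(outside) <= 25L &&
    !anyDuplicated(c(inside, outside))
  suppressWarnings(
    stats::wilcox.test(inside, outside, alternative = alternative,
                       exact = exact)$p.value
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(method = "BH")`: q-values are
#' capped at 1, monotone along the sorted p-values, and returned in the
#' original order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Enrichment of every gene set against every target list
#'
#' In `"ora"` mode each list in `all`/`up`/`down` is tested against each
#' set with [fisher_ora()]; BH adjustment is applied across sets within
#' each list (one q-value per set-by-list cell). Empty lists are reported
#' as not testable rather than given a p-value. In `"rank"` mode each set
#' is tested once against the supplied gene p-value map with
#' [wilcoxon_rank_enrichment()], BH-adjusted across sets.
#'
#' @param lists a `target_lists` object (ignored in rank mode).
#' @param collection a `gene_set_collection`.
#' @param universe character vector of measurable genes; defaults to the
#'   union of all list genes (ora mode) and is required there if that union
#'   is to be overridden.
#' @param mode `"ora"` or `"rank"`.
#' @param pvalues named gene -> p map, required when `mode = "rank"`.
#' @param alpha significance threshold on q (default 0.05).
#' @return data.frame with one row per (set, list) cell: `set_name`,
#'   `list_name`, `pvalue`, `qvalue`, `overlap_count`, `set_size`,
#'   `list_size`, `universe_size`, `testable`, `significant`.
#' @export
enrich_all <- function(lists, collection, universe = NULL,
                       mode = c("ora", "rank"), pvalues = NULL,
                       alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "gene_set_collection"),
            length(collection) > 0L)
  if (mode == "rank") {
    if (is.null(pvalues)) stop("rank mode needs a gene p-value map")
    scored <- canonical_symbol(names(pvalues))
    testable <- vapply(collection, function(s) {
      n_in <- sum(scored %in% s)
      n_in >= 1L && n_in < length(scored)
    }, logical(1))
    p <- rep(NA_real_, length(collection))
    p[testable] <- vapply(collection[testable], function(s)
      wilcoxon_rank_enrichment(pvalues, s), numeric(1))
    q <- rep(NA_real_, length(collection))
    q[testable] <- bh_adjust(p[testable])
    out <- data.frame(set_name = names(collection), list_name = "all",
                      pvalue = p, qvalue = q,
                      overlap_count = NA_integer_,
                      set_size = lengths(collection),
                      list_size = length(pvalues),
                      universe_size = length(pvalues),
                      testable = testable)
    out$significant <- !is.na(out$qvalue) & out$qvalue < alpha
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(inherits(lists, "target_lists"))
  if (is.null(universe)) universe <- lists$all
  universe <- unique(canonical_symbol(universe))
  res <- list()
  for (ln in c("all", "up", "down")) {
    lg <- lists[[ln]]
    if (length(lg) == 0L) {
      res[[ln]] <- data.frame(set_name = names(collection), list_name = ln,
                              pvalue = NA_real_, qvalue = NA_real_,
                              overlap_count = NA_integer_,
                              set_size = lengths(collection),
                              list_size = 0L,
                              universe_size = length(universe),
                              testable = FALSE)
      next
    }
    rows <- lapply(names(collection), function(nm) {
      r <- fisher_ora(lg, collection[[nm]], universe)
      cbind(data.frame(set_name = nm, list_name = ln), r)
    })
    tab <- do.call(rbind, rows)
    tab$qvalue <- bh_adjust(tab$pvalue)
    tab$testable <- TRUE
    res[[ln]] <- tab[, c("set_name", "list_name", "pvalue", "qvalue",
                         "overlap_count", "set_size", "list_size",
                         "universe_size", "testable")]
  }
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$qvalue) & out$qvalue < alpha
  rownames(out) <- NULL
  out
}
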