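# Relative gene expression: technical-replicate collapse, geNorm reference
# stability, and the delta-delta-Cq method with multiple reference genes.

#' Validate a long-format Cq table
#'
#' Expected columns: `sample_id`, `group`, `gene`, `replicate`, `cq`. Cq
#' values must be positive and finite (NA allowed for failed wells);
#' duplicate (sample, gene, replicate) rows are a fatal validation error.
#'
#' @param df data frame of raw quantification cycles.
#' @return The validated data frame, classed `cq_table`.
#' @export
cq_table <- function(df) {
  need <- c("sample_id", "group", "gene", "replicate", "cq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("Cq table is missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(df$sample_id, df$gene, df$replicate, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, gene, replicate) rows in Cq table")
  ok <- is.na(df$cq) | (is.finite(df$cq) & df$cq > 0)
  if (!all(ok))
    stop("Cq values must be positive and finite (or NA for failed wells)")
  class(df) <- unique(c("cq_table", class(df)))
  df
}

#' Collapse technical replicates to one mean Cq per sample and gene
#'
#' Arithmetic mean of the available replicate Cq values for every
#' (sample, gene) pair, as used for all downstream statistics. Pairs with
#' fewer replicates than the table's modal count (missing or NA wells) are
#' tolerated with a warning; a pair with no usable replicate is fatal.
#' Optionally, replicates more than 0.5 cycles from the pair median can be
#' dropped first (off by default: plain averaging).
#'
#' @param table a [cq_table()] (or data frame with the same columns).
#' @param drop_outliers drop replicates > 0.5 cycles from the pair median
#'   before averaging (default `FALSE`).
#' @return Data frame with `sample_id`, `group`, `gene`, `cq` (mean) and
#'   `n_replicates`.
#' @export
collapse_triplicates <- function(table, drop_outliers = FALSE) {
  table <- cq_table(as.data.frame(table))
  table <- table[!is.na(table$cq), , drop = FALSE]
  key <- interaction(table$sample_id, table$gene, drop = TRUE)
  if (nrow(table) == 0L) stop("no usable Cq values in table")

  rows <- lapply(split(table, key), function(d) {
    cq <- d$cq
    if (drop_outliers && length(cq) > 2L) {
      keep <- abs(cq - stats::median(cq)) <= 0.5
      if (any(keep)) cq <- cq[keep]
    }
    data.frame(sample_id = d$sample_id[1L], group = d$group[1L],
               gene = d$gene[1L], cq = mean(cq), n_replicates = length(cq))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  modal <- max(out$n_replicates)
  short <- out$n_replicates < modal
  if (any(short))
    warning(sprintf("%d (sample, gene) pair(s) have fewer than %d replicates",
                    sum(short), modal))
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

cq_matrix <- function(collapsed, genes = NULL) {
  if (!is.matrix(collapsed)) {
    if (!all(c("sample_id", "gene", "cq") %in% names(collapsed)))
      stop("expected a collapsed Cq data frame or a samples x genes matrix")
    m <- tapply(collapsed$cq, list(collapsed$sample_id, collapsed$gene), mean)
  } else {
    m <- collapsed
  }
  if (!is.null(genes)) {
    miss <- setdiff(genes, colnames(m))
    if (length(miss) > 0L)
      stop("genes not present in Cq data: ", paste(miss, collapse = ", "))
    m <- m[, genes, drop = FALSE]
  }
  m
}

#' geNorm M stability of candidate reference genes
#'
#' Classical geNorm definition: for genes j and k, the per-sample pairwise
#' log2 expression ratio is `A_jk = Cq_k - Cq_j`; `V_jk` is its standard
#' deviation over samples; and `M_j` is the mean of `V_jk` over all other
#' candidates k. Lower M means a more stable reference. The conventional
#' acceptance thresholds are M < 1.0 for tissue samples and M < 0.5 for cell
#' cultures.
#'
#' @param cq collapsed Cq data (a [collapse_triplicates()] result or a
#'   samples x genes matrix of mean Cq).
#' @param candidates character vector of at least two candidate gene names.
#' @return Data frame `gene`, `m`, `stable_tissue` (M < 1), `stable_culture`
#'   (M < 0.5), ordered by increasing M.
#' @export
genorm_m <- function(cq, candidates) {
  if (length(candidates) < 2L)
    stop("geNorm needs at least two candidate genes")
  m <- cq_matrix(cq, candidates)
  if (anyNA(m))
    stop("every candidate gene must be measured in every sample")
  if (nrow(m) < 2L)
    stop("geNorm needs at least two samples per gene")
  mv <- vapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(vapply(others, function(k) stats::sd(m[, k] - m[, j]), numeric(1)))
  }, numeric(1))
  out <- data.frame(gene = candidates, m = unname(mv),
                    stable_tissue = unname(mv) < 1.0,
                    stable_culture = unname(mv) < 0.5)
  out[order(out$m), , drop = FALSE]
}

#' Relative expression by the delta-delta-Cq method
#'
#' Per sample, `dCq = Cq_target - mean(Cq over reference genes)` (arithmetic
#' mean of reference Cq, equivalent to geometric-mean expression
#' normalization). Per target gene, `ddCq = dCq - centre`, where the centre
#' is the mean dCq over control-group samples (or a single calibrator
#' sample's dCq when `calibrator_sample` is given). Fold change is
#' `2^(-ddCq)`, assuming perfect doubling per cycle, so the control group's
#' geometric-mean fold is exactly 1.
#'
#' @param table a raw [cq_table()] (replicates are collapsed internally) or
#'   an already collapsed data frame.
#' @param targets character vector of target gene names.
#' @param references character vector of reference gene names (non-empty,
#'   disjoint from `targets`).
#' @param control_group group label whose samples define ddCq = 0.
#' @param calibrator_sample optional single sample id used as the centring
#'   calibrator instead of the control-group mean.
#' @return A `ddcq_result` data frame: one row per (sample, target) with
#'   `sample_id`, `group`, `gene`, `dcq`, `ddcq`, `fold`.
#' @export
relative_expression_ddcq <- function(table, targets, references, control_group,
                                     calibrator_sample = NULL) {
  if (length(references) == 0L) stop("need at least one reference gene")
  both <- intersect(targets, references)
  if (length(both) > 0L)
    stop("gene(s) listed as both target and reference: ",
         paste(both, collapse = ", "))
  df <- as.data.frame(table)
  if ("replicate" %in% names(df)) df <- collapse_triplicates(df)
  groups <- tapply(as.character(df$group), df$sample_id, function(g) g[1L])
  m <- cq_matrix(df, c(targets, references))

  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning("sample(s) dropped for missing genes: ",
            paste(rownames(m)[!complete], collapse = ", "))
    m <- m[complete, , drop = FALSE]
  }
  samples <- rownames(m)
  grp <- unname(groups[samples])
  in_control <- grp == control_group
  if (!any(in_control))
    stop("control group '", control_group, "' has no samples")

  ref_mean <- rowMeans(m[, references, drop = FALSE])
  rows <- lapply(targets, function(g) {
    dcq <- m[, g] - ref_mean
    centre <- if (is.null(calibrator_sample)) {
      mean(dcq[in_control])
    } else {
      if (!calibrator_sample %in% samples)
        stop("calibrator sample '", calibrator_sample, "' not found")
      dcq[samples == calibrator_sample]
    }
    ddcq <- dcq - centre
    data.frame(sample_id = samples, group = grp, gene = g,
               dcq = unname(dcq), ddcq = unname(ddcq),
               fold = 2^(-unname(ddcq)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "control_group") <- control_group
  attr(out, "references") <- references
  class(out) <- unique(c("ddcq_result", class(out)))
  out
}

#' Per-group fold-change summary of a ddCq result
#'
#' The group-level fold change is `2^(-mean(ddCq))` over the group's samples
#' — the geometric mean of per-sample folds, which is the natural summary on
#' the log2 scale of the assay.
#'
#' @param ddcq a [relative_expression_ddcq()] result.
#' @return Data frame `group`, `gene`, `n`, `mean_ddcq`, `fold`.
#' @export
ddcq_group_summary <- function(ddcq) {
  stopifnot(inherits(ddcq, "ddcq_result"))
  sp <- split(ddcq, list(ddcq$group, ddcq$gene), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(group = d$group[1L], gene = d$gene[1L], n = nrow(d),
               mean_ddcq = mean(d$ddcq), fold = 2^(-mean(d$ddcq)))))
  rownames(out) <- NULL
  out[order(out$gene, out$group), , drop = FALSE]
}
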