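# Transposable-element content of genes/introns and the correlations
# between gene length, TE proportion and genome size.

#' TE profile of a gene model
#'
#' Computes the percent of the gene (or of its introns only) covered by TE
#' annotations, on the interval union so overlapping or split records never
#' double-count, plus the class composition of TE bp. Overlaps between
#' classes are resolved by the priority retrotransposon > DNA transposon >
#' helitron > unclassified. Annotations extending outside the gene span are
#' clipped with a warning.
#'
#' @param model a [gene_model()].
#' @param annotations data.frame from [parse_repeatmasker_out()]. Intervals
#'   are interpreted on the model's scaffold when `target` equals the
#'   model's scaffold (and mapped through strand/span onto the gene), else
#'   directly on the gene's coordinate frame.
#' @param denominator `"gene"` (default) or `"intron"`: whether
#'   `te_fraction` is relative to the full gene length or to total intron
#'   length.
#' @return list of class `te_profile`: `taxon`, `gene_id`, `te_fraction`
#'   (percent), `te_bp`, `class_fractions` (percents of TE bp per class,
#'   summing to 100 when TE bp > 0), `ltr_split` (Gypsy/Copia/other
#'   percents of retrotransposon bp).
#' @export
te_profile <- function(model, annotations, denominator = c("gene", "intron")) {
  denominator <- match.arg(denominator)
  glen <- nchar(model$gene_seq)
  ann <- annotations
  if (nrow(ann) > 0L && !is.na(model$scaffold) &&
      any(ann$target == model$scaffold)) {
    ann <- ann[ann$target == model$scaffold, , drop = FALSE]
    if (model$strand == "+") {
      s <- ann$start - model$span[1L]; e <- ann$end - model$span[1L]
    } else {
      s <- model$span[2L] - ann$end; e <- model$span[2L] - ann$start
    }
    ann$start <- s; ann$end <- e
  }
  if (nrow(ann) > 0L && (any(ann$start < 0L) || any(ann$end > glen))) {
    warning("TE annotation(s) outside the gene span were clipped")
    ann$start <- pmax(ann$start, 0L)
    ann$end <- pmin(ann$end, glen)
  }
  ann <- ann[!is.na(ann$start) & ann$end > ann$start, , drop = FALSE]

  classes <- c("retrotransposon", "DNA_transposon", "helitron", "unclassified")
  to_ir <- function(d) IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
  union_all <- if (nrow(ann)) to_ir(ann) else IRanges::IRanges()
  te_bp <- sum(IRanges::width(union_all))

  class_bp <- stats::setNames(numeric(4), classes)
  claimed <- IRanges::IRanges()
  for (cl in classes) {  # priority order
    d <- ann[ann$te_class == cl, , drop = FALSE]
    if (nrow(d) == 0L) next
    ir <- IRanges::setdiff(to_ir(d), claimed)
    class_bp[cl] <- sum(IRanges::width(ir))
    claimed <- IRanges::reduce(c(claimed, ir))
  }

  retro <- ann[ann$te_class == "retrotransposon", , drop = FALSE]
  ltr_bp <- c(Gypsy = 0, Copia = 0, other = 0)
  if (nrow(retro) > 0L) {
    sf <- ifelse(retro$superfamily %in% c("Gypsy", "Copia"),
                 retro$superfamily, "other")
    for (g in unique(sf))
      ltr_bp[g] <- sum(IRanges::width(to_ir(retro[sf == g, , drop = FALSE])))
  }

  denom_len <- if (denominator == "gene") glen
               else sum(interval_widths(model$introns))
  structure(list(
    taxon = model$taxon, gene_id = model$gene_id,
    te_bp = te_bp,
    te_fraction = if (denom_len > 0L) 100 * te_bp / denom_len else NA_real_,
    class_fractions = if (te_bp > 0L) 100 * class_bp / sum(class_bp)
                      else class_bp,
    ltr_split = if (sum(ltr_bp) > 0) 100 * ltr_bp / sum(ltr_bp) else ltr_bp
  ), class = "te_profile")
}

#' TE profiles of many models as a table
#'
#' @param models list of [gene_model()].
#' @param annotations either one annotation data.frame (filtered per model
#'   by scaffold) or a named list keyed by taxon.
#' @inheritParams te_profile
#' @return data.frame, one row per model, with percent columns.
#' @export
te_profile_table <- function(models, annotations, denominator = "gene") {
  do.call(rbind, lapply(models, function(m) {
    ann <- if (is.data.frame(annotations)) annotations
           else annotations[[m$taxon]] %||% annotations[[1L]][0L, ]
    p <- te_profile(m, ann, denominator = denominator)
    data.frame(taxon = p$taxon, gene_id = p$gene_id,
               gene_length = nchar(m$gene_seq), te_bp = p$te_bp,
               te_fraction_pct = p$te_fraction,
               retrotransposon_pct = p$class_fractions[["retrotransposon"]],
               dna_transposon_pct = p$class_fractions[["DNA_transposon"]],
               helitron_pct = p$class_fractions[["helitron"]],
               unclassified_pct = p$class_fractions[["unclassified"]],
               gypsy_pct = p$ltr_split[["Gypsy"]],
               copia_pct = p$ltr_split[["Copia"]],
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson r with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 3`, each with nonzero variance.
#' @return list with `r`, `p`, `n`, `t`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("constant vector: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n, t = t)
}

#' Correlation report: gene length vs TE fraction and genome size
#'
#' Computes Pearson r and p for (gene length, TE fraction) -- both over all
#' profiled genes and excluding TE-free genes -- and (gene length, genome
#' size). Pairs with fewer than 3 complete records are skipped with a
#' warning.
#'
#' @param profiles data.frame from [te_profile_table()] (needs
#'   `gene_length` and `te_fraction_pct`).
#' @param genome_sizes optional data.frame (`taxon`, `genome_size`) or
#'   named vector.
#' @return data.frame with one row per test: `pair`, `r`, `p`, `n`.
#' @export
correlation_report <- function(profiles, genome_sizes = NULL) {
  rows <- list()
  try_pair <- function(name, x, y) {
    res <- tryCatch(pearson_correlation(x, y), error = function(e) {
      warning(sprintf("correlation '%s' skipped: %s", name,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res))
      rows[[length(rows) + 1L]] <<- data.frame(
        pair = name, r = res$r, p = res$p, n = res$n,
        stringsAsFactors = FALSE)
  }
  try_pair("gene_length~te_fraction",
           profiles$gene_length, profiles$te_fraction_pct)
  nz <- profiles$te_bp > 0
  if (sum(nz, na.rm = TRUE) >= 3L)
    try_pair("gene_length~te_fraction_nonzero",
             profiles$gene_length[nz], profiles$te_fraction_pct[nz])
  if (!is.null(genome_sizes)) {
    if (!is.data.frame(genome_sizes))
      genome_sizes <- data.frame(taxon = names(genome_sizes),
                                 genome_size = as.numeric(genome_sizes))
    gs <- genome_sizes$genome_size[match(profiles$taxon, genome_sizes$taxon)]
    try_pair("gene_length~genome_size", profiles$gene_length, gs)
  }
  if (length(rows) == 0L)
    return(data.frame(pair = character(0), r = numeric(0), p = numeric(0),
                      n = integer(0)))
  do.call(rbind, rows)
}
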