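#' Penetrance of a phenotype in one replicate
#'
#' `100 * abnormal / scored`, kept at full precision; rounding happens only
#' at report time (nearest integer, halves up, so 21 of 24 reports as 88%).
#'
#' @param abnormal number of embryos with the phenotype.
#' @param scored number of embryos scored (>= 1).
#' @return Penetrance in percent.
#' @export
penetrance <- function(abnormal, scored) {
  abnormal <- assert_count(abnormal, "abnormal")
  scored <- assert_count(scored, "scored", 1L)
  if (abnormal > scored) stop("'abnormal' cannot exceed 'scored'")
  100 * abnormal / scored
}

#' @rdname penetrance
#' @param x penetrance value(s) in percent.
#' @param digits decimals to display.
#' @return `format_penetrance`: character vector like `"88"`.
#' @export
format_penetrance <- function(x, digits = 0) {
  formatC(display_round(x, digits), format = "f", digits = digits)
}

#' Aggregate replicate penetrances for one gene
#'
#' Mean and sample standard deviation (n-1 denominator) of per-replicate
#' penetrances, as reported in screen summary tables (one decimal at
#' display). With a single replicate the sd is undefined and flagged.
#'
#' @param records data frame with columns `scored` and `abnormal` (one row
#'   per replicate), or a numeric vector of penetrances in percent.
#' @return List: `mean`, `sd`, `n`, `penetrances`, `sd_defined`.
#' @export
aggregate_gene <- function(records) {
  pen <- if (is.numeric(records)) records else
    mapply(penetrance, records$abnormal, records$scored)
  n <- length(pen)
  if (n < 1L) stop("no replicates")
  list(mean = mean(pen), sd = if (n > 1) stats::sd(pen) else NA_real_,
       n = n, penetrances = pen, sd_defined = n > 1)
}

#' Candidate and confirmation calls for one gene
#'
#' A dsRNA passes when the penetrance of every one of its independent
#' replicates strictly exceeds 30% (on the unrounded value). The gene is a
#' candidate if at least one dsRNA passes, and confirmed if at least two
#' distinct dsRNAs (targeting different regions of the transcript) pass.
#'
#' @param records data frame with `dsrna_id`, `scored`, `abnormal` (and
#'   optionally `replicate`) for one gene.
#' @param threshold penetrance threshold, percent (strict).
#' @return Object of class `gene_call`: per-replicate penetrances,
#'   aggregate mean/sd, `candidate`, `confirmed`, passing dsRNA ids.
#' @export
candidate_call <- function(records, threshold = 30) {
  stopifnot(all(c("dsrna_id", "scored", "abnormal") %in% names(records)))
  pen <- mapply(penetrance, records$abnormal, records$scored)
  pass <- tapply(pen, records$dsrna_id, function(p) all(p > threshold))
  agg <- aggregate_gene(pen)
  structure(list(penetrances = pen, mean = agg$mean, sd = agg$sd,
                 n = agg$n, dsrna_pass = pass,
                 candidate = any(pass), confirmed = sum(pass) >= 2L),
            class = "gene_call")
}

#' Summarize a screen table into per-gene calls
#'
#' @param table `ScreenRecord` data frame: `gene`, `dsrna_id`, `replicate`,
#'   `scored`, `abnormal`.
#' @param threshold candidate threshold, percent.
#' @return Data frame with one row per gene: mean and sd penetrance,
#'   replicate count, candidate and confirmed flags.
#' @export
screen_summary <- function(table, threshold = 30) {
  stopifnot(all(c("gene", "dsrna_id", "scored", "abnormal") %in%
                  names(table)))
  genes <- split(table, table$gene)
  rows <- lapply(names(genes), function(g) {
    call <- candidate_call(genes[[g]], threshold)
    data.frame(gene = g,
               mean_penetrance = call$mean, sd_penetrance = call$sd,
               n_replicates = call$n,
               display = paste0(format_penetrance(call$mean, 1), "±",
                                format_penetrance(call$sd, 1)),
               candidate = call$candidate, confirmed = call$confirmed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a replicate table of screen counts
#'
#' Abnormal counts are binomial draws at each gene/dsRNA's true penetrance,
#' emulating injection replicates (default 21 embryos scored per replicate,
#' the screen's average).
#'
#' @param genes character vector of gene names.
#' @param true_penetrance numeric vector in `[0, 1]`, recycled over genes.
#' @param n_dsrna dsRNAs per gene.
#' @param n_replicates replicates per dsRNA.
#' @param n_scored embryos scored per replicate.
#' @param seed integer seed or `NULL`.
#' @return `ScreenRecord` data frame.
#' @export
simulate_screen_table <- function(genes, true_penetrance, n_dsrna = 1,
                                  n_replicates = 4, n_scored = 21,
                                  seed = NULL) {
  stopifnot(length(genes) >= 1L)
  p <- rep_len(true_penetrance, length(genes))
  if (any(p < 0 | p > 1)) stop("true_penetrance must lie in [0, 1]")
  assert_count(n_dsrna, "n_dsrna", 1L)
  assert_count(n_replicates, "n_replicates", 1L)
  assert_count(n_scored, "n_scored", 1L)
  with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(n_replicates),
                        dsrna = seq_len(n_dsrna),
                        gene_i = seq_along(genes))
    data.frame(
      gene = genes[grid$gene_i],
      dsrna_id = sprintf("%s_ds%d", genes[grid$gene_i], grid$dsrna),
      replicate = grid$replicate,
      scored = n_scored,
      abnormal = stats::rbinom(nrow(grid), n_scored, p[grid$gene_i]))
  })
}
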