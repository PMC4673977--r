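#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a calling run into one row per genotyped site
#'
#' @param x A `bs_calls` object.
#' @param variants_only Keep only variant genotypes (default) or all genotyped
#'   candidate sites.
#' @param ... Unused.
#' @return Tibble with `chrom`, `pos`, `ref`, `genotype`, `depth`, `err`,
#'   `posterior`, `phred_quality`, `filter`, `is_variant`.
#' @method tidy bs_calls
#' @export
tidy.bs_calls <- function(x, variants_only = TRUE, ...) {
  out <- x$calls
  if (variants_only) out <- out[out$is_variant, , drop = FALSE]
  cols <- c("chrom", "pos", "ref", "genotype", "depth", "err",
            "posterior", "phred_quality", "filter", "is_variant")
  as_tibble(out[intersect(cols, names(out))])
}

#' One-row summary of a calling run
#'
#' @param x A `bs_calls` object.
#' @param ... Unused.
#' @return Tibble with read, candidate, variant and methylation counts and the
#'   mean genotype quality of variant calls.
#' @method glance bs_calls
#' @export
glance.bs_calls <- function(x, ...) {
  v <- x$calls[x$calls$is_variant, , drop = FALSE]
  tibble(
    n_reads = x$counters$reads_total,
    n_admitted = x$counters$reads_admitted,
    n_candidates = x$counters$candidates,
    n_variants = x$counters$variants,
    n_pass = sum(v$filter == "PASS"),
    mean_gq = if (nrow(v)) mean(v$phred_quality) else NA_real_,
    n_meth_records = nrow(x$meth)
  )
}

#' @rdname tidy.bs_calls
#' @method tidy bs_eval
#' @export
tidy.bs_eval <- function(x, ...) x$matched

#' @rdname glance.bs_calls
#' @method glance bs_eval
#' @export
glance.bs_eval <- function(x, ...) x$summary

#' Plot genotype quality against depth for genotyped sites
#'
#' @param object A `bs_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bs_calls
#' @export
autoplot.bs_calls <- function(object, ...) {
  d <- tidy(object, variants_only = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$depth, y = .data$phred_quality,
                                  colour = .data$filter,
                                  shape = .data$is_variant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "retained depth", y = "genotype quality (Phred)",
                  colour = "FILTER", shape = "variant") +
    ggplot2::theme_minimal()
}

#' Histogram of methylation levels by context
#'
#' @param meth Methylation tibble from [bs_call()] (or a `bs_calls` object).
#' @param min_depth Minimum informative depth for a site to be shown.
#' @return A ggplot.
#' @export
plot_methylation_levels <- function(meth, min_depth = 5) {
  if (inherits(meth, "bs_calls")) meth <- meth$meth
  d <- meth[!is.na(meth$context) & meth$total_count >= min_depth, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~context, scales = "free_y") +
    ggplot2::labs(x = "methylation level", y = "cytosines") +
    ggplot2::theme_minimal()
}
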