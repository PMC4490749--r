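# broom-style tidiers for fitted objects.

#' Tidy a fitted multiple-QTL model
#'
#' One row per model term (locus or interaction) with effect estimates and,
#' when available, per-term variance attribution.
#'
#' @param x A `qtl_model`.
#' @param ... Unused.
#' @return A tibble: `term`, `chr`, `pos_cM`, `a`, `d`, `pct_var`, `lod_drop`.
#' @method tidy qtl_model
#' @export
tidy.qtl_model <- function(x, ...) {
  if (nrow(x$loci) == 0) {
    return(tibble(term = character(), chr = character(), pos_cM = numeric(),
                  a = numeric(), d = numeric(), pct_var = numeric(),
                  lod_drop = numeric()))
  }
  base <- tibble(
    term = sprintf("%s@%.1f", x$loci$chr, x$loci$pos_cM),
    chr = x$loci$chr, pos_cM = x$loci$pos_cM,
    a = x$loci$a, d = x$loci$d
  )
  if (nrow(x$interactions) > 0) {
    base <- dplyr::bind_rows(base, tibble(
      term = sprintf(
        "%s@%.1f:%s@%.1f",
        x$loci$chr[x$interactions$q1], x$loci$pos_cM[x$interactions$q1],
        x$loci$chr[x$interactions$q2], x$loci$pos_cM[x$interactions$q2]
      ),
      chr = NA_character_, pos_cM = NA_real_, a = NA_real_, d = NA_real_
    ))
  }
  if (!is.null(x$terms)) {
    base <- dplyr::left_join(
      base, dplyr::select(x$terms, "term", "pct_var", "lod_drop"),
      by = "term"
    )
  } else {
    base$pct_var <- NA_real_
    base$lod_drop <- NA_real_
  }
  base
}

#' One-row summary of a fitted multiple-QTL model
#'
#' @param x A `qtl_model`.
#' @param ... Unused.
#' @return A tibble: `n_loci`, `n_interactions`, `lod`, `plod`, `pct_var_total`, `n`.
#' @method glance qtl_model
#' @export
glance.qtl_model <- function(x, ...) {
  tss <- x$rss0 # note: rss0 is the covariates-only RSS, not raw TSS
  tibble(
    n_loci = nrow(x$loci),
    n_interactions = nrow(x$interactions),
    lod = x$lod,
    plod = x$plod,
    pct_var_total = if (nrow(x$loci)) 100 * (x$rss0 - x$rss) / x$rss0 else 0,
    n = x$n
  )
}

#' Tidy a genome scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return The scan as a plain tibble (`chr`, `pos_cM`, `is_marker`, `lod`).
#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) {
  as_tibble(x[, c("chr", "pos_cM", "is_marker", "lod")])
}

#' Plot a genome scan
#'
#' LOD curve along the genome, faceted by chromosome; an optional horizontal
#' line marks a significance threshold.
#'
#' @param object A `qtl_scan`.
#' @param threshold Optional LOD threshold to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_scan
#' @export
autoplot.qtl_scan <- function(object, threshold = NULL, ...) {
  df <- tidy(object)
  df$chr <- factor(df$chr, levels = unique(df$chr))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(1, "pt"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = as.numeric(threshold),
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot refinement LOD curves of a fitted model
#'
#' @param object A refined `qtl_model` (see [refine_positions()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qtl_model
#' @export
autoplot.qtl_model <- function(object, ...) {
  if (is.null(object$refinement)) {
    abort("model has no refinement curves; run refine_positions() first")
  }
  df <- object$refinement
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chr), scales = "free") +
    ggplot2::labs(x = "position (cM)", y = "model LOD") +
    ggplot2::theme_minimal()
}

#' Plot one slice of a voxel volume
#'
#' @param volume A `voxel_volume`.
#' @param z Slice index (default: middle slice).
#' @param what `"data"` for grayscale, `"phase"` for ground-truth labels.
#' @return A ggplot object.
#' @export
plot_slice <- function(volume, z = NULL, what = c("data", "phase")) {
  what <- match.arg(what)
  z <- z %||% ceiling(dim(volume$data)[3] / 2)
  arr <- if (what == "data") volume$data else volume$truth$phase
  df <- expand.grid(x = seq_len(dim(arr)[1]), y = seq_len(dim(arr)[2]))
  df$value <- as.vector(arr[, , z])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = sprintf("slice z = %d (%s)", z, what)) +
    ggplot2::theme_void()
}
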