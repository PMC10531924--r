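# ggplot2 displays. NMR convention: both chemical-shift axes run from high
# to low ppm.

#' @export
autoplot.peak_list <- function(object, ...) {
  tbl <- tibble::new_tibble(as.list(object), nrow = nrow(object))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$delta_h, y = .data$delta_c)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(delta * H ~ "(ppm)"),
                  y = expression(delta * C ~ "(ppm)")) +
    ggplot2::theme_minimal()
}

#' Overlay of a matched fingerprint pair
#'
#' Reference peaks in black, query peaks in blue, paired peaks joined by a
#' segment; the residues with the largest combined-shift differences are
#' labelled.
#'
#' @param object An `hsqc_match`.
#' @param n_labels How many of the top-ranked differences to label.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hsqc_match <- function(object, n_labels = 3, ...) {
  pairs <- object$pairs
  top <- head(pairs, n_labels)
  ggplot2::ggplot(pairs) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$delta_h_ref, y = .data$delta_c_ref,
      xend = .data$delta_h_query, yend = .data$delta_c_query),
      colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(x = .data$delta_h_ref,
                                     y = .data$delta_c_ref),
                        colour = "black", size = 2) +
    ggplot2::geom_point(ggplot2::aes(x = .data$delta_h_query,
                                     y = .data$delta_c_query),
                        colour = "steelblue", size = 2, shape = 17) +
    ggplot2::geom_text(data = top, ggplot2::aes(
      x = .data$delta_h_ref, y = .data$delta_c_ref, label = .data$label),
      vjust = -1, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = expression(delta * H ~ "(ppm)"),
                  y = expression(delta * C ~ "(ppm)"),
                  title = if (!is.na(object$verdict)) {
                    sprintf("%s (max %.3f, threshold %.3f)",
                            object$verdict, object$max_distance,
                            object$threshold)
                  } else NULL) +
    ggplot2::theme_minimal()
}

#' Logo-style display of a position frequency matrix
#'
#' Letters are stacked per column with heights proportional to
#' `frequency x information content`, the standard sequence-logo scaling
#' (letter glyph sizes track the stack heights approximately).
#'
#' @param object A `pfm` from [build_pfm()].
#' @param min_freq Letters below this frequency are dropped from the stack.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pfm <- function(object, min_freq = 0.02, ...) {
  tbl <- tidy(object)
  tbl$height <- tbl$freq * tbl$ic
  tbl <- tbl[tbl$freq >= min_freq & tbl$height > 0, ]
  tbl <- dplyr::arrange(tbl, .data$position, .data$height)
  tbl <- dplyr::group_by(tbl, .data$position)
  tbl <- dplyr::mutate(tbl, ymax = cumsum(.data$height),
                       ymid = .data$ymax - .data$height / 2)
  tbl <- dplyr::ungroup(tbl)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$position, y = .data$ymid,
                                    label = .data$residue)) +
    ggplot2::geom_text(ggplot2::aes(size = .data$height,
                                    colour = .data$residue),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1.5, 8)) +
    ggplot2::scale_x_continuous(breaks = unique(tbl$position)) +
    ggplot2::labs(x = "motif position", y = "bits") +
    ggplot2::theme_minimal()
}
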