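#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Heatmap of a pair-score matrix
#'
#' Antibody positions (rows, faceted by chain) against antigen residues
#' (columns), filled by predicted contact probability.
#'
#' @param object A `pair_score_tbl` from [score_all_pairs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pair_score_tbl
#' @export
autoplot.pair_score_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$ab <- paste0(df$ab_chain, df$position, df$ins_letter)
  df$ag <- paste0(df$ag_chain, df$ag_resno, df$ag_ins)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$ag, unique(.data$ag)),
    y = factor(.data$ab, rev(unique(.data$ab))), fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "P(contact)") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$ab_chain), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "antigen residue", y = "antibody position (IMGT)") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 5),
                   axis.text.y = ggplot2::element_text(size = 5))
}

#' Per-residue SAP profile
#'
#' @param object A [sap_scores()] tibble.
#' @param ... Unused.
#' @return A ggplot object; positive bars flag aggregation-prone residues.
#' @export
plot_sap_profile <- function(object, ...) {
  df <- dplyr::mutate(object, idx = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$idx, y = .data$sap,
                                   fill = .data$sap > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#c0392b",
                                          `FALSE` = "#7f8c8d")) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chain), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "residue (chain order)", y = "SAP") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Conservation comparison of two paratopes
#'
#' One tile per paratope position of antibody A, coloured by its deepest
#' conservation level in antibody B's complex.
#'
#' @param object A [compare_paratopes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_tbl
#' @export
autoplot.conservation_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$level <- dplyr::case_when(
    df$germline_identical ~ "germline identical",
    df$identical_sidechain ~ "identical side-chain",
    df$shared ~ "shared position",
    TRUE ~ "unique to A")
  df$level <- factor(df$level, c("unique to A", "shared position",
                                 "identical side-chain", "germline identical"))
  df$pos <- paste0(df$chain_type, df$position, df$ins_letter)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$pos, unique(.data$pos)),
                                   y = 1, fill = .data$level)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 3) +
    ggplot2::scale_fill_brewer(palette = "Blues", name = NULL) +
    ggplot2::labs(x = "paratope position (IMGT)", y = NULL) +
    ggplot2::theme_minimal(base_size = 10) +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
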