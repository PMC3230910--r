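#' Run the full screen analysis
#'
#' Chains the pipeline on a measured screen: plate normalization, QC,
#' main-effect fit, interaction estimation, per-pair testing, and network
#' construction, writing every intermediate table to `outdir` together with
#' a run log.
#'
#' @param input a `screen_table`, a `simulated_screen`, or a path to a
#'   long-format table.
#' @param outdir output directory (created if needed).
#' @param format_spec column mapping for file input.
#' @param grouping replicate grouping for the fit (default `"biological"`).
#' @param options [robust_options()] for the fit.
#' @param test which t-test feeds the interaction graph (default
#'   `"moderated"`).
#' @param p_cut,w_cut,c_cut network thresholds (defaults 0.1, 0.3, 0.8).
#' @param node_class optional named node class labels for graph export.
#' @return Invisibly, a list with all intermediate objects (`screen`,
#'   `normalized`, `qc`, `fit`, `interactions`, `tests`, `pvalue_graph`,
#'   `correlation`, `graphs`).
#' @export
run_screen_analysis <- function(input, outdir,
                                format_spec = default_format_spec(),
                                grouping = "biological",
                                options = robust_options(),
                                test = "moderated",
                                p_cut = 0.1, w_cut = 0.3, c_cut = 0.8,
                                node_class = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  screen <- if (is.character(input)) read_screen_table(input, format_spec)
            else if (inherits(input, "simulated_screen")) input$screen
            else input
  stopifnot(inherits(screen, "screen_table"))

  nscreen <- normalize_plates(screen)
  write_screen_table_normalized(nscreen, file.path(outdir, "normalized.tsv"))
  utils::write.table(
    data.frame(plate = names(nscreen$centers), mu = unname(nscreen$centers)),
    file.path(outdir, "plate_centers.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  qc <- qc_report(nscreen)
  write_qc_report(qc, file.path(outdir, "qc"))

  fit <- fit_main_effects(nscreen, grouping = grouping, options = options)
  est <- estimate_interactions(nscreen, fit)
  write_fit_tables(fit, est, outdir)

  trend <- fit_diagnostic_trend(est)
  utils::write.table(trend, file.path(outdir, "fit_diagnostic_trend.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  tests <- pair_tests(est)
  utils::write.table(as.data.frame(tests), file.path(outdir, "tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ss <- schweder_spjotvoll(tests$p_moderated)
  utils::write.table(ss$points, file.path(outdir, "pvalue_graph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ig <- interaction_graph(est$W, tests, p_cut = p_cut, w_cut = w_cut,
                          test = test, node_class = node_class)
  export_graph(ig, file.path(outdir, "interaction_edges.tsv"), "edgelist")
  export_graph(ig, file.path(outdir, "interaction_graph.graphml"), "graphml")

  C <- profile_correlation(est$W)
  utils::write.table(C, file.path(outdir, "correlation_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  cg <- correlation_graph(C, c_cut = c_cut, node_class = node_class)
  export_graph(cg, file.path(outdir, "correlation_edges.tsv"), "edgelist")

  log <- c(paste0("crisscross ",
                  as.character(utils::packageVersion("crisscross"))),
           paste0("R ", R.version.string),
           paste0("grouping=", grouping, " loss=", options$loss,
                  " test=", test),
           paste0("p_cut=", p_cut, " w_cut=", w_cut, " c_cut=", c_cut),
           paste0("wells=", nrow(screen$wells),
                  " pairs=", length(pair_index(screen))),
           paste0("false_null_estimate=", ss$n_false_null))
  writeLines(log, file.path(outdir, "run_log.txt"))

  invisible(list(screen = screen, normalized = nscreen, qc = qc, fit = fit,
                 interactions = est, tests = tests, pvalue_graph = ss,
                 correlation = C,
                 graphs = list(interaction = ig, correlation = cg)))
}

## normalized long-format writer: adds the normalized-value column
write_screen_table_normalized <- function(nscreen, path) {
  w <- nscreen$wells
  role <- stats::setNames(nscreen$reagents$control_role, nscreen$reagents$id)
  ctrl <- ifelse(role[w$reagent_row] != "none", role[w$reagent_row],
                 ifelse(role[w$reagent_col] != "none", role[w$reagent_col],
                        "none"))
  out <- data.frame(plate = w$plate, well = well_name(w$row, w$col),
                    reagent_row = w$reagent_row, reagent_col = w$reagent_col,
                    value = w$readout, normalized = w$value,
                    biorep = w$bio_rep, techrep = w$tech_rep,
                    control = unname(ctrl), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
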