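#' Run the full selection-signature pipeline
#'
#' Orchestrates the stages -- substitution mapping, per-site and
#' per-domain contrasts, radicality scan, convergence detection and the
#' branch-model ML fits with LRTs -- and writes one TSV report per
#' stage plus a run log.  Stage order and report shapes mirror the
#' tables of a typical branch-model selection study.
#'
#' @param config Either a YAML file path or a list with elements:
#'   `alignment`, `tree`, `groups` (file paths), optional `domains`,
#'   `properties` (file paths), and optional scalars `genetic_code`
#'   (default `"vertebrate_mitochondrial"`), `label_mode`
#'   (default `"clade"`), `alpha` (0.05), `z_alpha` (0.001),
#'   `category_min` (6), `window` (20), `min_lineages` (3), `seed` (1).
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(genetic_code = "vertebrate_mitochondrial",
                   label_mode = "clade", alpha = 0.05, z_alpha = 0.001,
                   category_min = 6L, window = 20L, min_lineages = 3L,
                   seed = 1L)
  config <- utils::modifyList(defaults, config)
  stopifnot(config$alpha > 0, config$alpha < 1,
            config$z_alpha > 0, config$z_alpha < 1, config$window >= 1)
  for (f in c("alignment", "tree", "groups")) {
    if (is.null(config[[f]])) stop("[config] missing required path: ", f)
    if (!file.exists(config[[f]])) {
      stop("[config] file not found for '", f, "': ", config[[f]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  code <- stage("genetics_io", load_genetic_code(config$genetic_code))
  aln <- stage("genetics_io", read_codon_alignment(config$alignment, code))
  groups <- stage("genetics_io", read_group_table(config$groups))
  ltree <- stage("genetics_io",
                 label_branches(config$tree, groups, config$label_mode))

  states <- stage("substitution_mapping", fitch_states(aln, ltree, code))
  events <- stage("substitution_mapping", map_events(states, ltree, code))
  write_events(events, file.path(out_dir, "events.tsv"))

  site_ns <- stage("contrast_stats",
                   site_contrast(events, ltree, aln$sites, "nonsynonymous",
                                 config$alpha))
  site_s <- stage("contrast_stats",
                  site_contrast(events, ltree, aln$sites, "synonymous",
                                config$alpha))
  write_contrast(rbind(site_ns, site_s),
                 file.path(out_dir, "site_contrasts.tsv"))
  results <- list(events = events, site_contrasts = rbind(site_ns, site_s))

  if (!is.null(config$domains)) {
    domains <- stage("contrast_stats",
                     read_domain_map(config$domains, aln$sites))
    dom <- rbind(
      stage("contrast_stats",
            domain_contrast(events, ltree, domains, "nonsynonymous",
                            config$alpha)),
      stage("contrast_stats",
            domain_contrast(events, ltree, domains, "synonymous",
                            config$alpha)))
    write_contrast(dom, file.path(out_dir, "domain_contrasts.tsv"))
    results$domain_contrasts <- dom
  }

  props <- stage("radicality", read_property_table(config$properties))
  cat_map <- stage("radicality", categorize_changes(props, code))
  zsc <- stage("radicality",
               window_z_scores(events, cat_map, config$window, aln$sites))
  utils::write.table(zsc, file.path(out_dir, "window_zscores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rad <- stage("radicality",
               radical_events(events, zsc, cat_map, config$category_min,
                              config$z_alpha))
  conv <- stage("convergence",
                find_convergent(events, ltree, aln, code,
                                min_lineages = config$min_lineages,
                                radical = rad))
  utils::write.table(conv, file.path(out_dir, "convergent_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$zscores <- zsc
  results$radical <- rad
  results$convergent <- conv

  bm <- stage("codon_model_ml", branch_model_tests(aln, ltree, code))
  fit_tab <- do.call(rbind, lapply(bm$fits, function(f) {
    data.frame(model = f$model, lnL = f$lnL, kappa = f$kappa,
               omega_fg = f$omega_fg, omega_bg = f$omega_bg,
               scale = f$scale, status = f$status,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(fit_tab, file.path(out_dir, "model_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lrt_tab <- data.frame(
    comparison = c("b_free_vs_M0", "b_free_vs_b_neut"),
    statistic = c(bm$lrt_free_vs_m0$statistic, bm$lrt_free_vs_neut$statistic),
    df = c(bm$lrt_free_vs_m0$df, bm$lrt_free_vs_neut$df),
    p = c(bm$lrt_free_vs_m0$p, bm$lrt_free_vs_neut$p),
    stringsAsFactors = FALSE)
  utils::write.table(lrt_tab, file.path(out_dir, "lrt.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  results$model_fits <- bm

  log_lines <- c(
    paste0("selsig ", as.character(utils::packageVersion("selsig"))),
    paste0("seed: ", config$seed),
    paste0("genetic_code: ", config$genetic_code),
    paste0("label_mode: ", config$label_mode),
    paste0("alpha: ", config$alpha, "  z_alpha: ", config$z_alpha,
           "  category_min: ", config$category_min,
           "  window: ", config$window,
           "  min_lineages: ", config$min_lineages))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
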