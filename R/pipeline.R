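#' Pipeline run configuration
#'
#' Bundles the analysis parameters. Defaults reproduce the standard
#' settings: fat window -200..-60 HU, subpleural depth 10 mm, alpha 0.05.
#'
#' @param hu_low,hu_high fat window bounds (HU).
#' @param depth_mm subpleural depth (mm).
#' @param lobe_labels named integer vector of lobe labels.
#' @param alpha significance level for cohort statistics.
#' @param seed optional integer seed for simulation commands.
#' @param output_format `"json"` or `"csv"`.
#' @return Object of class `run_config`.
#' @export
run_config <- function(hu_low = -200, hu_high = -60, depth_mm = 10,
                       lobe_labels = default_lobe_labels(), alpha = 0.05,
                       seed = NULL, output_format = c("json", "csv")) {
  structure(
    list(window = hu_window(hu_low, hu_high), depth_mm = depth_mm,
         lobe_labels = lobe_labels, alpha = alpha, seed = seed,
         output_format = match.arg(output_format)),
    class = "run_config"
  )
}

config_echo <- function(config) {
  list(hu_low = config$window$lower, hu_high = config$window$upper,
       depth_mm = config$depth_mm,
       lobe_labels = as.list(config$lobe_labels), alpha = config$alpha,
       seed = config$seed)
}

flatten_result <- function(res) {
  out <- fat_quant_fields(res$whole)
  if (!is.null(res$compartments)) {
    out <- c(out, fat_quant_fields(res$compartments$subpleural, "subpleural"),
             fat_quant_fields(res$compartments$nonsubpleural,
                              "nonsubpleural"))
  }
  if (!is.null(res$lobar)) {
    for (nm in names(res$lobar$per_lobe))
      out <- c(out, fat_quant_fields(res$lobar$per_lobe[[nm]], nm))
    for (nm in names(res$lobar$per_group))
      out <- c(out, fat_quant_fields(res$lobar$per_group[[nm]],
                                     paste0("group_", nm)))
  }
  out
}

write_result <- function(res, config, out_path) {
  payload <- c(list(config = config_echo(config)), flatten_result(res))
  if (config$output_format == "json") {
    jsonlite::write_json(payload, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    flat <- payload
    flat$config <- NULL
    cfg <- config_echo(config)
    cfg$lobe_labels <- paste(names(config$lobe_labels), config$lobe_labels,
                             sep = "=", collapse = ";")
    cfg$seed <- cfg$seed %||% NA
    write.csv(cbind(as.data.frame(cfg), as.data.frame(flat)), out_path,
              row.names = FALSE)
  }
  invisible(out_path)
}

#' Run the fat-quantification pipeline on one subject
#'
#' Loads image and mask(s), refuses geometry mismatches, quantifies
#' whole-lung fat, the subpleural/nonsubpleural compartments and (if a lobe
#' mask is given) the lobar breakdown, and optionally writes a JSON/CSV
#' result that embeds the exact parameters used. Deterministic: the same
#' inputs and config always produce byte-identical output files.
#'
#' @param config a [run_config()].
#' @param image_path NIfTI file or DICOM series directory.
#' @param lung_mask_path NIfTI lung mask (any positive label = lung).
#' @param lobe_mask_path optional NIfTI lobe mask.
#' @param out_path optional output file path.
#' @return List with `whole` (`fat_quant`), `compartments`
#'   (`compartment_quant`), optionally `lobar` (`lobar_quant`), invisibly if
#'   `out_path` is given.
#' @export
run_pipeline <- function(config = run_config(), image_path, lung_mask_path,
                         lobe_mask_path = NULL, out_path = NULL) {
  stopifnot(inherits(config, "run_config"))
  image <- load_volume(image_path)
  lung <- load_mask(lung_mask_path)
  res <- list(
    whole = compute_ctpfav(image, lung, config$window),
    compartments = compartment_quant(image, lung, config$window,
                                     depth_mm = config$depth_mm)
  )
  if (!is.null(lobe_mask_path)) {
    lobes <- load_mask(lobe_mask_path, label_map = config$lobe_labels)
    res$lobar <- lobar_quant(image, lobes, config$window,
                             label_map = config$lobe_labels)
  }
  if (!is.null(out_path)) {
    write_result(res, config, out_path)
    return(invisible(res))
  }
  res
}

#' Write a cohort statistics report
#'
#' Runs [run_battery()] on a cohort table (data.frame or CSV path) and
#' writes a JSON report plus, optionally, a CSV of the pairwise table.
#'
#' @param table data.frame or path to a CSV cohort table.
#' @param metric metric column name.
#' @param config a [run_config()] (supplies `alpha`).
#' @param out_path optional JSON output path.
#' @param pairwise_csv optional CSV output path for the post hoc table.
#' @return The `cohort_test_report`, invisibly if `out_path` is given.
#' @export
run_cohort_stats <- function(table, metric = "pfi_pct",
                             config = run_config(), out_path = NULL,
                             pairwise_csv = NULL) {
  if (is.character(table)) {
    if (!file.exists(table))
      pf_stop("pulmofat_io_error", "cohort table '", table, "' not found")
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  rep <- run_battery(table, metric, alpha = config$alpha)
  if (!is.null(out_path)) {
    payload <- list(config = config_echo(config), metric = metric,
                    normality = rep$normality, omnibus = rep$omnibus,
                    posthoc = rep$posthoc, descriptives = rep$descriptives)
    jsonlite::write_json(payload, out_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  if (!is.null(pairwise_csv)) write.csv(rep$posthoc, pairwise_csv,
                                        row.names = FALSE)
  if (!is.null(out_path)) invisible(rep) else rep
}
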