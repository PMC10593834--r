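#' Run the end-to-end dual-score screen from a configuration
#'
#' Wires the pipeline together: build the tendon signature from a two-group
#' expression matrix (or load signatures from a GMT file), restrict both
#' signatures to the library universe, score the library on the stemness
#' and tendon axes, select the top-rank intersection, and write the screen
#' table plus a JSON run manifest. Any stage error aborts with the stage
#' name and the offending input path; reruns with an identical
#' configuration are byte-identical.
#'
#' @param config a named list, or a path to a YAML/JSON file holding one.
#'   Recognised fields: \code{library} (TSV path, required),
#'   \code{library_metadata} (optional TSV), \code{signatures} (GMT path)
#'   with \code{stemness_signature}/\code{tendon_signature} set names, or
#'   alternatively \code{expression} + \code{sample_groups} TSV paths from
#'   which the tendon signature is built (then \code{signatures} must hold
#'   the stemness set); \code{p_threshold} (default 0.05),
#'   \code{max_up}/\code{max_down}, \code{top_k_stemness}/
#'   \code{top_k_tendon} (default 5\% of the library),
#'   \code{orientations} (named list, default stemness = mimic,
#'   tendon = reverse), \code{seed}, \code{output_dir} (required).
#' @return The \code{screen_table}, invisibly; side effects are
#'   \code{screen_table.tsv} and \code{manifest.json} in
#'   \code{output_dir}.
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(is.list(config))
  stage <- function(name, path, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed",
           if (!is.null(path)) paste0(" (input: ", path, ")") else "",
           ": ", conditionMessage(e), call. = FALSE))
  }
  need <- function(field) {
    if (is.null(config[[field]])) stop("config field '", field,
                                       "' is required")
    config[[field]]
  }
  out_dir <- need("output_dir")
  lib_path <- need("library")
  for (f in c("library", "library_metadata", "signatures", "expression",
              "sample_groups"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path for '", f, "' does not exist: ", config[[f]])
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  lib <- stage("load_library", lib_path,
               read_library_tsv(lib_path, config$library_metadata))

  gmt_sigs <- if (!is.null(config$signatures))
    stage("load_signatures", config$signatures, read_gmt(config$signatures))

  if (!is.null(config$expression)) {
    tendon_sig <- stage("build_tendon_signature", config$expression, {
      expr <- read_expression_tsv(config$expression)
      grp <- read_sample_groups(need("sample_groups"))
      grp <- grp[colnames(expr)]
      compute_deg_signature(
        expr, grp,
        p_threshold = config$p_threshold %||% 0.05,
        max_up = config$max_up %||% Inf,
        max_down = config$max_down %||% Inf,
        name = "tendon")$signature
    })
  } else {
    tendon_sig <- stage("load_signatures", config$signatures,
                        gmt_sigs[[need("tendon_signature")]])
    if (is.null(tendon_sig))
      stop("tendon signature '", config$tendon_signature,
           "' not found in ", config$signatures)
  }
  if (is.null(gmt_sigs))
    stop("config field 'signatures' (GMT path) is required for the ",
         "stemness axis")
  stemness_sig <- stage("load_signatures", config$signatures,
                        gmt_sigs[[need("stemness_signature")]])
  if (is.null(stemness_sig))
    stop("stemness signature '", config$stemness_signature,
         "' not found in ", config$signatures)

  dropped <- character()
  restrict_logged <- function(sig) {
    withCallingHandlers(
      restrict_to_universe(sig, lib$universe),
      warning = function(w) {
        dropped <<- c(dropped, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  stemness_sig <- stage("restrict_signatures", lib_path,
                        restrict_logged(stemness_sig))
  tendon_sig <- stage("restrict_signatures", lib_path,
                      restrict_logged(tendon_sig))

  orientations <- unlist(config$orientations %||%
                           list(stemness = "mimic", tendon = "reverse"))
  tab <- stage("dual_score_screen", lib_path, suppressWarnings(
    dual_score_screen(lib, stemness_sig, tendon_sig,
                      top_k_stemness = config$top_k_stemness,
                      top_k_tendon = config$top_k_tendon,
                      orientations = orientations)))

  table_path <- file.path(out_dir, "screen_table.tsv")
  stage("write_outputs", table_path, write_screen_table(tab, table_path))

  sig_hash <- function(sig) {
    tmp <- tempfile(fileext = ".gmt")
    on.exit(unlink(tmp))
    write_gmt(sig, tmp)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(
    config = config,
    seed = config$seed,
    n_compounds = nrow(lib$delta),
    n_genes = length(lib$universe),
    screen = attr(tab, "config"),
    signature_hashes = list(stemness = sig_hash(stemness_sig),
                            tendon = sig_hash(tendon_sig)),
    dropped_signature_genes = dropped,
    n_selected = sum(tab$selected),
    selected = tab$compound_id[tab$selected])
  stage("write_outputs", file.path(out_dir, "manifest.json"),
        jsonlite::write_json(manifest,
                             file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE,
                             null = "null", digits = NA))
  invisible(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file; format chosen by extension
#'   (\code{.json} vs \code{.yaml}/\code{.yml}).
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
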