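#' Serialize a run configuration into an output directory
#'
#' Every command-line run writes its full configuration, the package
#' version, and a timestamp into `run_metadata.json` in the output
#' directory so results are auditable and reproducible.
#'
#' @param config Named list of configuration values.
#' @param out_dir Output directory (created if absent).
#' @return Path of the metadata file, invisibly.
#' @export
write_run_metadata <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    config = config,
    package = "formsem",
    version = as.character(utils::packageVersion("formsem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Locate the command-line entry point
#'
#' The package ships a thin `Rscript` front end with subcommands
#' (`pairwise`, `sweep`, `synth`, `inspect`) over the exported functions.
#' This returns its installed path, e.g. for
#' `Rscript $(Rscript -e 'cat(formsem::formsem_cli_path())') synth --out d`.
#'
#' @return Path to the installed CLI script.
#' @export
formsem_cli_path <- function() {
  system.file("cli", "formsem.R", package = "formsem", mustWork = TRUE)
}
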