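#' Run the full mixing analysis pipeline
#'
#' Orchestrates the stages of the analysis in order: natural-abundance
#' correction -> replicate averaging -> calibration interpolation (with
#' error propagation) -> conversion to (chi4, Q) -> rejection-sampled
#' isoform chains for each protofilament -> optionally a helically
#' replicated filament model annotated with those chains. Configuration
#' is a plain list (or a YAML/JSON file of the same shape), and the
#' returned bundle carries a manifest from which an identical re-run can
#' be reproduced.
#'
#' Config fields (all optional unless noted): `calibration` (path to a
#' calibration CSV or a tibble; required unless `synthetic = TRUE`),
#' `measured` (path/tibble of scheme-labeled curves; required unless
#' synthetic), `synthetic` (logical: generate inputs with
#' [synthesis_config()] defaults), `brackets`, `window`, `na_correct`,
#' `seed`, `chain_length` (default 360), `chain_tol` (default 0.01),
#' `n_protofilaments` (default 2), `build_filament` (logical), `filament_seed`
#' (atom tibble or structure path for the helix seed), `rise`, `twist`,
#' `out_dir` (when set, estimate JSON, chains and filament are written
#' there).
#'
#' @param config A list, or a path to a YAML or JSON config file.
#' @return A list of class `pipeline_result`: `fit` (a `mixing_fit`),
#'   `chains`, `chain_stats`, `filament` (or NULL), `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  cfg <- utils::modifyList(
    list(synthetic = FALSE, brackets = list("4N3C" = c(0.30, 0.40),
                                            "3N4C" = c(0.50, 0.60)),
         window = c(8, 25), na_correct = TRUE, seed = 1L,
         chain_length = 360L, chain_tol = 0.01, n_protofilaments = 2L,
         build_filament = FALSE, rise = 4.7, twist = 1.0, out_dir = NULL),
    config)
  load_tbl <- function(x) if (is.character(x)) read_redor_csv(x) else as_tibble(x)
  if (isTRUE(cfg$synthetic)) {
    syn <- synthesis_config(seed = as.integer(cfg$seed))
    cal <- generate_calibration_series(syn)
    measured <- generate_seeded_dataset(syn)
  } else {
    if (is.null(cfg$calibration) || is.null(cfg$measured)) {
      abort("Config needs `calibration` and `measured` (or `synthetic = TRUE`).")
    }
    cal <- load_tbl(cfg$calibration)
    measured <- load_tbl(cfg$measured)
    if (!"fraction" %in% names(cal)) {
      abort("The calibration table must have a `fraction` column; required fractions are the bracketing values and 0 for the reference.")
    }
  }
  brackets <- purrr::map(cfg$brackets, as.numeric)
  fit <- estimate_full_dataset(measured, cal, brackets = brackets,
                               window = as.numeric(cfg$window),
                               na_correct = isTRUE(cfg$na_correct))
  p <- fit$probabilities
  chains <- purrr::map(seq_len(cfg$n_protofilaments), function(i) {
    simulate_until_match(p, length = cfg$chain_length, tol = cfg$chain_tol,
                         seed = as.integer(cfg$seed) + i)
  })
  names(chains) <- paste0("P", seq_along(chains))
  stats <- purrr::imap_dfr(chains, ~ dplyr::mutate(chain_stats(.x),
                                                   proto = .y, .before = 1))
  filament <- NULL
  if (isTRUE(cfg$build_filament)) {
    seed_atoms <- if (is.null(cfg$filament_seed)) {
      purrr::map_dfr(seq_len(cfg$n_protofilaments), function(i) {
        st <- generate_toy_protofilament(3, n_residues = 3)
        dplyr::mutate(dplyr::filter(st, .data$chain == "A"),
                      proto = paste0("P", i),
                      y = .data$y + (i - 1) * 12)
      })
    } else {
      as_atom_tibble(cfg$filament_seed)
    }
    filament <- replicate_helix(seed_atoms, n_monomers = cfg$chain_length,
                                rise = cfg$rise, twist = cfg$twist)
    filament <- assign_isoforms(filament, chains)
  }
  manifest <- list(
    config = cfg[setdiff(names(cfg), c("calibration", "measured", "filament_seed"))],
    inputs = list(
      calibration = if (is.character(config$calibration %||% NULL)) config$calibration else "in-memory",
      measured = if (is.character(config$measured %||% NULL)) config$measured else "in-memory"),
    seed = as.integer(cfg$seed),
    package_version = as.character(utils::packageVersion("fibrilmix")))
  result <- structure(
    list(fit = fit, chains = chains, chain_stats = stats,
         filament = filament, manifest = manifest),
    class = "pipeline_result")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_estimate_json(fit, file.path(cfg$out_dir, "estimate.json"))
    write_chain_fasta(chains, file.path(cfg$out_dir, "chains.fasta"))
    readr::write_csv(stats, file.path(cfg$out_dir, "chain_stats.csv"))
    if (!is.null(filament)) {
      write_filament_cif(filament, file.path(cfg$out_dir, "filament.cif"))
    }
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("fibrilmix pipeline result\n\n")
  print(x$fit)
  cat("\nAccepted chains:\n")
  print(as.data.frame(x$chain_stats), row.names = FALSE)
  if (!is.null(x$filament)) {
    cat("\n")
    print(x$filament)
  }
  invisible(x)
}

#' Read and write pipeline configuration files
#'
#' A single YAML (or JSON) file format is accepted by every pipeline
#' entry point; `write_pipeline_config()` then `read_pipeline_config()`
#' round-trips to an identical list.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return `read_pipeline_config()` returns the config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' not found.", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' @rdname read_pipeline_config
#' @param config Config list.
#' @export
write_pipeline_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}
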