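#' Default configuration
#'
#' Returns the full set of tunable parameters used across the package:
#' structure I/O, graph construction, network architecture, training and
#' lambda-schedule optimization. Every key can be overridden through
#' [alch_config()], either from a YAML file or from an R list.
#'
#' @return Named list of configuration values.
#' @export
alch_default_config <- function() {
  list(
    ## structure I/O
    pocket_cutoff_angstrom = 5.0,
    exclude_waters = TRUE,
    exclude_ions = TRUE,
    ## graph construction
    noncovalent_cutoff_angstrom = 4.5,
    d_dist_basis = 16L,
    ## architecture
    d_hidden = 128L,
    n_layers = 3L,
    d_lambda_basis = 16L,
    activation = "silu",
    pooling = "sum",
    ## training
    lr = 1e-3,
    weight_decay = 1e-4,
    warmup_steps = 500L,
    plateau_factor = 0.5,
    plateau_patience = 10L,
    early_stop_patience = 30L,
    batch_size = 64L,
    n_epochs = 300L,
    val_fraction = 0.2,
    epsilon_weight = 0.1,
    use_reliability_weights = TRUE,
    seed = 0L,
    ## free-energy assembly
    leg_signs = c(1, -1),
    ## lambda-schedule optimization
    lambda_threshold = 10,
    lambda_resolution = 0.001,
    gap_mode = "interval"
  )
}

#' Build an effective run configuration
#'
#' Merges, in order of increasing precedence: package defaults, an optional
#' YAML file, and an optional list of overrides. Unknown keys are rejected
#' so that typos never silently fall back to defaults.
#'
#' @param yaml_file Optional path to a YAML file with configuration keys.
#' @param overrides Optional named list of configuration values.
#' @return Named list with every key of [alch_default_config()].
#' @export
alch_config <- function(yaml_file = NULL, overrides = NULL) {
  cfg <- alch_default_config()
  apply_layer <- function(cfg, layer, src) {
    if (is.null(layer)) return(cfg)
    if (!is.list(layer) || (length(layer) > 0 && is.null(names(layer))))
      stop("configuration layer from ", src, " must be a named list")
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown) > 0)
      stop("unknown configuration key(s) from ", src, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(layer)) cfg[[k]] <- layer[[k]]
    cfg
  }
  if (!is.null(yaml_file)) {
    if (!file.exists(yaml_file)) stop("config file not found: ", yaml_file)
    cfg <- apply_layer(cfg, yaml::read_yaml(yaml_file), yaml_file)
  }
  cfg <- apply_layer(cfg, overrides, "overrides")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$pocket_cutoff_angstrom > 0,
    cfg$noncovalent_cutoff_angstrom > 0,
    cfg$d_hidden >= 1, cfg$n_layers >= 1, cfg$d_lambda_basis >= 2,
    cfg$lr > 0, cfg$weight_decay >= 0,
    cfg$plateau_factor > 0, cfg$plateau_factor < 1,
    cfg$plateau_patience >= 1, cfg$early_stop_patience >= 1,
    cfg$batch_size >= 1, cfg$epsilon_weight > 0,
    length(cfg$leg_signs) == 2, all(abs(cfg$leg_signs) == 1),
    cfg$lambda_threshold > 0,
    cfg$lambda_resolution > 0, cfg$lambda_resolution < 1,
    cfg$gap_mode %in% c("interval", "endpoint")
  )
  invisible(cfg)
}

#' Write the effective configuration next to an output
#'
#' Every command-line run serializes the configuration it actually used, so
#' results can be reproduced from the output directory alone.
#'
#' @param cfg Configuration list.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
alch_write_config <- function(cfg, path) {
  yaml::write_yaml(c(cfg, list(alchnet_version = as.character(utils::packageVersion("alchnet")))),
                   path)
  invisible(path)
}
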