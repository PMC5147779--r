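# Plain-text configuration and audit output.

#' Write a model/run configuration
#'
#' Serializes parameters, medium, mutant edits and run settings to a YAML
#' file with keyed sections (`params`, `medium`, `mutant`, `run`), so one
#' network definition can serve many runs.
#'
#' @param path output file
#' @param params parameter set (only non-default entries need be present)
#' @param medium medium name
#' @param mutant optional [mutant_spec()]
#' @param run optional list of run settings (seed, max_cells, t_stop, ...)
#' @return the path, invisibly
#' @export
write_config <- function(path, params = default_params(),
                         medium = "glucose", mutant = NULL, run = list()) {
  cfg <- list(version = 1L,
              params = unclass(params),
              medium = medium,
              run = run)
  if (!is.null(mutant)) {
    cfg$mutant <- list(name = mutant$name, edits = mutant$edits)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a configuration and build the network it describes
#'
#' @param path YAML file written by [write_config()] (hand-edited files
#'   with the same keys are fine; unknown parameter names are rejected)
#' @return list with `network`, `params`, `medium`, `mutant`, `run`
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) stop("config is missing the 'params' section")
  p <- do.call(default_params, cfg$params[names(cfg$params) %in%
                                            names(default_params())])
  unknown <- setdiff(names(cfg$params), names(default_params()))
  if (length(unknown)) stop("unknown parameter key(s): ",
                            paste(unknown, collapse = ", "))
  med <- medium_growth(cfg$medium %||% "glucose")
  net <- build_wildtype(p, med)
  mut <- NULL
  if (!is.null(cfg$mutant)) {
    mut <- mutant_spec(cfg$mutant$name, cfg$mutant$edits)
    net <- apply_mutant(net, mut)
  }
  list(network = net, params = p, medium = med, mutant = mut,
       run = cfg$run %||% list())
}

#' Export the expanded elementary-reaction list as TSV
#'
#' One row per reaction: id, `+`-joined reactants and products, rate
#' constant, multiplicity, volume-scaling tag and audit group.
#'
#' @param net a `yc_network`
#' @param path output file
#' @return the path, invisibly
#' @export
export_network_tsv <- function(net, path) {
  utils::write.table(reaction_table(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything that determines a run's output bytes: a hash of the
#' expanded reaction table and parameters, the master seed, and the stop
#' rule, so identical manifests imply identical outputs.
#'
#' @param net a `yc_network`
#' @param config a [culture_config()]
#' @return list with `config_hash`, `seed`, `n_species`, `n_reactions`,
#'   `medium`, `strain`, `stop`
#' @export
run_manifest <- function(net, config) {
  tab <- reaction_table(net)
  payload <- paste(c(apply(tab, 1, paste, collapse = "|"),
                     paste(names(net$params), unlist(net$params))),
                   collapse = "\n")
  hash <- sum(utf8ToInt(payload) *
                (seq_along(utf8ToInt(payload)) %% 977 + 1)) %% 2147483647
  list(config_hash = sprintf("%d", hash), seed = config$seed,
       n_species = nrow(net$species), n_reactions = nrow(tab),
       medium = net$medium$name,
       strain = net$genotype$label %||% "wild type",
       stop = list(max_cells = config$max_cells, t_stop = config$t_stop))
}
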