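#' Read a structure grammar from a YAML configuration file
#'
#' The configuration is a plain key-value file with a `grammar` section:
#'
#' ```yaml
#' grammar:
#'   n_range: [3, 4, 5]          # backbone lengths, explicit list
#'   acyl:
#'     carbons: [12, 14, 16, 18, 20, 22]
#'     double_bonds: [0, 1, 2, 3]
#'   allowed:                    # substituent codes per position
#'     R2: [H, Me]
#'     R3: [H, Ac, Cb]
#'     R4: [H, Cb]
#'     R5: [H, Ac]
#'     R6: [H, S, Fuc, MeFuc, FucS, Ac]
#' ```
#'
#' Omitted keys fall back to the [structure_grammar()] defaults.
#'
#' @param path Path to the YAML file.
#' @return A [structure_grammar()].
#' @export
read_grammar <- function(path) {
  cfg <- yaml::read_yaml(path)
  g <- cfg$grammar
  if (is.null(g)) stop("config has no 'grammar' section", call. = FALSE)
  args <- list()
  if (!is.null(g$n_range)) args$n_range <- as.integer(unlist(g$n_range))
  if (!is.null(g$acyl)) {
    args$acyl_library <- default_acyl_library(
      carbons = as.integer(unlist(g$acyl$carbons)),
      double_bonds = as.integer(unlist(g$acyl$double_bonds)))
  }
  if (!is.null(g$allowed)) {
    args$allowed <- lapply(g$allowed, function(x) as.character(unlist(x)))
  }
  do.call(structure_grammar, args)
}

#' Read a simulation configuration from a YAML file
#'
#' Reads the `simulation` section of the shared configuration file; its
#' keys mirror the arguments of [sim_config()], with `planted` given as a
#' list of `{structure, rt}` entries:
#'
#' ```yaml
#' simulation:
#'   planted:
#'     - {structure: "LCO-IV(C16:0,S)", rt: 6.2}
#'     - {structure: "CO4", rt: 2.4}
#'   noise_sd: 5
#'   dropout: 0
#'   seed: 42
#' ```
#'
#' @param path Path to the YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  s <- cfg$simulation
  if (is.null(s)) stop("config has no 'simulation' section", call. = FALSE)
  planted <- data.frame(
    structure = vapply(s$planted, `[[`, character(1), "structure"),
    rt = vapply(s$planted, function(p)
      if (is.null(p$rt)) NA_real_ else as.numeric(p$rt), numeric(1)))
  args <- s[setdiff(names(s), "planted")]
  if (!is.null(args$amplitude_range)) {
    args$amplitude_range <- as.numeric(unlist(args$amplitude_range))
  }
  do.call(sim_config, c(list(planted = planted), args))
}

#' Export a structure list as TSV (name, formula, neutral mass)
#'
#' @param structures List of `chito_structure` objects.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(structures, path) {
  if (inherits(structures, "chito_structure")) structures <- list(structures)
  df <- data.frame(
    name = vapply(structures, canonical_name, character(1)),
    formula = vapply(structures, function(s)
      formula_to_string(structure_formula(s)), character(1)),
    neutral_mass = vapply(structures, function(s)
      monoisotopic_mass(structure_formula(s)), numeric(1))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
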