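#' Solvent-accessible surface area by Shrake-Rupley sampling
#'
#' Rolls a probe sphere (default 1.4 Angstrom, a water molecule) over the
#' heavy atoms of the model. Test points are distributed on each expanded
#' sphere by a deterministic golden-section spiral; the exposed fraction of
#' points gives the atomic area. Standard van der Waals radii are used
#' (C 1.70, N 1.55, O 1.52, S 1.80 A); hydrogens are ignored.
#'
#' @param model A [structure_model][parse_structure].
#' @param probe_radius Probe radius in Angstrom (> 0).
#' @param n_points Number of test points per atom.
#' @return List with `per_atom`, `per_residue` (named by residue serial) and
#'   `total` areas in Angstrom^2.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.numeric(probe_radius) || probe_radius <= 0)
    stop("probe_radius must be positive", call. = FALSE)
  if (nrow(model$atoms) < 1L) stop("model has no atoms", call. = FALSE)
  radii <- unname(vdw_radii[model$atoms$element])
  radii[is.na(radii)] <- 1.70
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  per_atom <- sasa_shrake_rupley_cpp(xyz, radii, probe_radius, as.integer(n_points))
  per_residue <- tapply(per_atom, model$atoms$residue, sum)
  per_residue <- stats::setNames(as.numeric(per_residue), names(per_residue))
  list(per_atom = per_atom, per_residue = per_residue, total = sum(per_atom))
}

#' Net charge of a sequence
#'
#' Simple pH ~7 convention: +1 per Lys/Arg, -1 per Asp/Glu; histidine and the
#' chain termini are neutral.
#'
#' @param sequence One-letter amino-acid string (standard 20-letter alphabet).
#' @return Integer-valued net charge in elementary charges.
#' @export
compute_net_charge <- function(sequence) {
  aa <- check_sequence(sequence)
  sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
}

#' Chain volume from residue composition
#'
#' Sum of mean per-residue volumes ([residue_volumes]); additive over
#' concatenation and independent of conformation.
#'
#' @inheritParams compute_net_charge
#' @return Volume in Angstrom^3.
#' @export
compute_volume <- function(sequence) {
  aa <- check_sequence(sequence)
  sum(residue_volumes[aa])
}

check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0)
    stop("sequence must be a non-empty string", call. = FALSE)
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), amino_acids)
  if (length(bad) > 0)
    stop(sprintf("non-standard residue letter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  aa
}

#' Surface hydrophobicity
#'
#' Fraction of the total solvent-accessible surface area contributed by
#' residues in the hydrophobic set ([hydrophobic_residues]).
#'
#' @param model A [structure_model][parse_structure].
#' @param sasa Result of [compute_sasa()] on the same model; computed if `NULL`.
#' @return Fraction in [0, 1].
#' @export
surface_hydrophobicity <- function(model, sasa = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(sasa)) sasa <- compute_sasa(model)
  if (sasa$total <= 0) stop("total surface area is zero", call. = FALSE)
  serials <- as.integer(names(sasa$per_residue))
  hydro <- model$residues$aa[serials] %in% hydrophobic_residues
  sum(sasa$per_residue[hydro]) / sasa$total
}

#' Extract the eleven structural variables from a structure model
#'
#' Computes net charge, volume, surface area, secondary-structure counts
#' (alpha helix, beta sheet, coil), their percentages of chain length, the
#' percentage of secondary structure (%alpha + %beta, exactly) and surface
#' hydrophobicity.
#'
#' @param model A [structure_model][parse_structure].
#' @param id Identifier stored in the output row.
#' @param label Class label: `"natural"`, `"random"` or `"unknown"`.
#' @return One-row data frame with columns `id`, the eleven variables
#'   (see [feature_variables()]) and `label`.
#' @export
extract_features <- function(model, id = "protein", label = "unknown") {
  stopifnot(inherits(model, "structure_model"))
  label <- match.arg(label, c("natural", "random", "unknown"))
  len <- nrow(model$residues)
  ss <- assign_secondary_structure(model)
  sasa <- compute_sasa(model)
  n_alpha <- sum(ss == "H"); n_beta <- sum(ss == "E"); n_coil <- sum(ss == "C")
  pct_alpha <- 100 * n_alpha / len
  pct_beta <- 100 * n_beta / len
  data.frame(
    id = id,
    net_charge = compute_net_charge(model$sequence),
    volume = compute_volume(model$sequence),
    surface = sasa$total,
    coil = n_coil,
    beta = n_beta,
    alpha = n_alpha,
    pct_alpha = pct_alpha,
    pct_beta = pct_beta,
    pct_coil = 100 * n_coil / len,
    pct_secondary = pct_alpha + pct_beta,
    surface_hydrophobicity = surface_hydrophobicity(model, sasa),
    label = label,
    stringsAsFactors = FALSE)
}

#' Read and write feature tables
#'
#' A feature table has one row per protein: an `id` column, the eleven
#' structural variables and a `label` column. On disk the variables carry
#' their display names (see [feature_variables()]).
#'
#' @param table Feature table (data frame).
#' @param path File path for the CSV.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the feature table.
#' @export
write_feature_table <- function(table, path) {
  check_feature_table(table)
  out <- table[, c("id", names(feature_variables()), "label")]
  names(out) <- c("id", unname(feature_variables()), "label")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  vars <- feature_variables()
  missing <- setdiff(c("id", unname(vars), "label"), names(raw))
  if (length(missing) > 0)
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  out <- raw[, c("id", unname(vars), "label")]
  names(out) <- c("id", names(vars), "label")
  out
}

# a feature table needs id + label plus >= 1 numeric variable column;
# the canonical eleven-variable layout is enforced by the CSV reader/writer
check_feature_table <- function(table, require_label = TRUE) {
  need <- c("id", if (require_label) "label")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  vars <- feature_vars_of(table)
  if (length(vars) == 0)
    stop("feature table has no variable columns", call. = FALSE)
  nonnum <- vars[!vapply(table[vars], is.numeric, logical(1))]
  if (length(nonnum) > 0)
    stop(sprintf("non-numeric variable column(s): %s",
                 paste(nonnum, collapse = ", ")), call. = FALSE)
  invisible(table)
}

feature_vars_of <- function(table) setdiff(names(table), c("id", "label"))
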