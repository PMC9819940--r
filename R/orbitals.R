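# Molecular-orbital analysis: LCAO atomic-orbital weights, MO-energy
# distributions over an ensemble, and the correlation of the departing-MO
# energy with the valence-orbital energy of the free halide.

#' Highest occupied atomic-orbital (sHOMO) energies of free halogen atoms
#'
#' Reference energies, in eV, of the highest occupied (spin) orbital of the
#' free halogen atoms F, Cl and Br from unrestricted long-range-corrected DFT
#' calculations. These are fixed inputs used to correlate the ensemble-average
#' departing-MO energy with the halide identity; they are never computed here.
#'
#' @format Named numeric vector (eV).
#' @export
halide_shomo_ev <- c(F = -15.2, Cl = -11.5, Br = -10.5)

#' Create an LCAO coefficient block
#'
#' Holds the real LCAO coefficients c_ji of one or more molecular orbitals
#' together with the AO-to-atom and atom-to-type maps needed to decompose an
#' MO into per-atom-type weights.
#'
#' @param coefficients N_AO x N_MO numeric matrix of real LCAO coefficients;
#'   column names label the MOs (e.g. `"HOMO"`, `"LUMO"`).
#' @param ao_atom Integer vector, length N_AO: the (1-based) atom each AO sits
#'   on.
#' @param atom_type Character vector, one element/type label per atom.
#' @param mo_energies Optional named numeric vector of MO energies in eV.
#' @return An object of class `coeff_block`.
#' @export
coeff_block <- function(coefficients, ao_atom, atom_type, mo_energies = NULL) {
  coefficients <- as.matrix(coefficients)
  ao_atom <- as.integer(ao_atom)
  if (nrow(coefficients) != length(ao_atom))
    stop("coefficients must have one row per AO in ao_atom")
  if (any(ao_atom < 1L) || any(ao_atom > length(atom_type)))
    stop("every AO must map to an atom with a type")
  structure(list(coefficients = coefficients, ao_atom = ao_atom,
                 atom_type = as.character(atom_type),
                 mo_energies = mo_energies),
            class = "coeff_block")
}

.resolve_mo <- function(block, mo) {
  if (is.character(mo)) {
    j <- match(mo, colnames(block$coefficients))
    if (is.na(j)) stop("unknown MO label: ", mo)
    j
  } else {
    mo <- as.integer(mo)
    if (mo < 1L || mo > ncol(block$coefficients))
      stop("MO index out of range: ", mo)
    mo
  }
}

#' Atomic-orbital weight of an atom type in a molecular orbital
#'
#' Computes omega_{alpha,i} = (1/N_alpha) * sum_j |c_ji|^2 delta_{j,alpha}:
#' the sum of squared LCAO coefficients over all AOs sitting on atoms of type
#' alpha, divided by the number N_alpha of such atoms. Because the AO basis is
#' not orthonormal the weight is approximate and need not stay below 1; it is
#' always >= 0, and larger values indicate a larger contribution of that
#' atom type to the MO.
#'
#' @param block A `coeff_block`.
#' @param mo MO column index or label.
#' @param atom_type Type label alpha (e.g. `"N"`, `"Br"`).
#' @return The weight omega (single non-negative number).
#' @export
ao_weight <- function(block, mo, atom_type) {
  j <- .resolve_mo(block, mo)
  n_alpha <- sum(block$atom_type == atom_type)
  if (n_alpha == 0L) stop("no atoms of type '", atom_type, "' in block")
  on_alpha <- block$atom_type[block$ao_atom] == atom_type
  sum(block$coefficients[on_alpha, j]^2) / n_alpha
}

#' Write / read a coefficient block as long-format CSV
#'
#' Columns: `ao_index`, `atom_index`, `atom_type`, `mo_index`, `coefficient`.
#' MO labels are carried through `mo_index` when the matrix has column names.
#'
#' @param block A `coeff_block`.
#' @param path CSV path.
#' @return `write_coeff_block_csv` returns the rows written invisibly;
#'   `read_coeff_block_csv` returns a `coeff_block`.
#' @export
write_coeff_block_csv <- function(block, path) {
  co <- block$coefficients
  mo_names <- colnames(co)
  if (is.null(mo_names)) mo_names <- as.character(seq_len(ncol(co)))
  df <- data.frame(
    ao_index = rep(seq_len(nrow(co)), times = ncol(co)),
    atom_index = rep(block$ao_atom, times = ncol(co)),
    atom_type = rep(block$atom_type[block$ao_atom], times = ncol(co)),
    mo_index = rep(mo_names, each = nrow(co)),
    coefficient = as.numeric(co))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @rdname write_coeff_block_csv
#' @export
read_coeff_block_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ao_index", "atom_index", "atom_type", "mo_index", "coefficient")
  if (!all(need %in% names(df)))
    stop("coefficient CSV must have columns ", paste(need, collapse = ", "))
  mo_names <- unique(df$mo_index)
  ao_idx <- sort(unique(df$ao_index))
  co <- matrix(0, nrow = length(ao_idx), ncol = length(mo_names),
               dimnames = list(NULL, mo_names))
  co[cbind(match(df$ao_index, ao_idx), match(df$mo_index, mo_names))] <-
    df$coefficient
  first <- !duplicated(df$ao_index)
  ao_atom <- df$atom_index[first][order(df$ao_index[first])]
  n_atoms <- max(ao_atom)
  atom_type <- character(n_atoms)
  atom_type[df$atom_index] <- df$atom_type
  coeff_block(co, ao_atom, atom_type)
}

.mo_energy_column <- function(which = c("initial", "final")) {
  which <- match.arg(which)
  if (which == "initial") "e_mo_initial_ev" else "e_mo_final_ev"
}

#' Ensemble statistics of an MO energy
#'
#' Mean and sample standard deviation, over all snapshots that report it, of
#' the energy of the MO the excitation starts from (`which = "initial"`, the
#' HOMO for the S1 excitation of these compounds) or ends in
#' (`which = "final"`, the LUMO).
#'
#' @param records List of `snapshot_record` objects or an excitation table.
#' @param which `"initial"` or `"final"`.
#' @param state_index Excited state to interrogate (default 1, i.e. S1).
#' @return List with `mean`, `sd` and `n` (entries used).
#' @export
mo_energy_stats <- function(records, which = c("initial", "final"),
                            state_index = 1L) {
  col <- .mo_energy_column(which)
  tab <- if (is.data.frame(records)) records else excitation_table(records)
  x <- tab[tab$state_index == as.integer(state_index), col]
  x <- x[!is.na(x)]
  if (!length(x))
    stop("no ", match.arg(which), " MO energies for state ", state_index)
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0, n = length(x))
}

#' Frequency histogram of an MO energy over the ensemble
#'
#' Plain counting histogram (weight one per snapshot, unlike the f/dE-weighted
#' spectrum) of an MO energy, on bins of the given width aligned to multiples
#' of the width and covering the data range.
#'
#' @inheritParams mo_energy_stats
#' @param bin_width_ev Bin width in eV (default 0.1).
#' @return List with `bin_edges` (eV) and `counts`.
#' @export
mo_energy_histogram <- function(records, which = c("initial", "final"),
                                state_index = 1L, bin_width_ev = 0.1) {
  if (bin_width_ev <= 0) stop("bin_width_ev must be > 0")
  col <- .mo_energy_column(which)
  tab <- if (is.data.frame(records)) records else excitation_table(records)
  x <- tab[tab$state_index == as.integer(state_index), col]
  x <- x[!is.na(x)]
  if (!length(x))
    stop("no ", match.arg(which), " MO energies for state ", state_index)
  lo <- floor(min(x) / bin_width_ev) * bin_width_ev
  hi <- ceiling(max(x) / bin_width_ev) * bin_width_ev
  if (hi <= lo) hi <- lo + bin_width_ev
  edges <- seq(lo, hi, by = bin_width_ev)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  list(bin_edges = edges, counts = tabulate(idx, nbins = length(edges) - 1L))
}

#' Correlation of the departing-MO energy with the free-halide sHOMO energy
#'
#' Tests the design rule behind the bathochromic series: the higher the
#' highest occupied orbital of the free halogen atom, the higher the
#' ensemble-average energy of the MO the excitation starts from, and hence the
#' smaller the excitation energy. Pearson correlation is used (only a handful
#' of substituents exist); the monotonicity flag carries the scientific claim.
#'
#' @param shomo_ev Numeric vector of free-halide sHOMO energies (eV), one per
#'   substituent (see [halide_shomo_ev]).
#' @param mean_moi_ev Ensemble-average departing-MO energies (eV), same order.
#' @return List with `r` (Pearson), `monotonic` (`TRUE` when `mean_moi_ev` is
#'   nondecreasing in `shomo_ev`) and `n`.
#' @export
halide_trend <- function(shomo_ev, mean_moi_ev) {
  if (length(shomo_ev) != length(mean_moi_ev))
    stop("shomo_ev and mean_moi_ev must have equal length")
  if (length(shomo_ev) < 3L) stop("need at least 3 substituent pairs")
  if (stats::sd(shomo_ev) == 0 || stats::sd(mean_moi_ev) == 0)
    stop("zero variance: correlation undefined")
  ord <- order(shomo_ev)
  list(r = stats::cor(shomo_ev, mean_moi_ev),
       monotonic = !is.unsorted(mean_moi_ev[ord]),
       n = length(shomo_ev))
}
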