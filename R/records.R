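# Snapshot-record data model and JSON-Lines interchange format.
#
# A snapshot record is one geometry drawn from a thermal simulation together
# with the excited states computed at that geometry. The excitations are held
# as a data frame with one row per excited state and fixed columns:
# state_index, delta_e_ev, osc_strength, e_mo_initial_ev, e_mo_final_ev.

EXCITATION_COLS <- c("state_index", "delta_e_ev", "osc_strength",
                     "e_mo_initial_ev", "e_mo_final_ev")

#' Create an excitation-entry table
#'
#' Builds the per-snapshot excited-state table: one row per state, with the
#' excitation energy, oscillator strength and (optionally) the energies of the
#' molecular orbitals the excitation starts from and ends in.
#'
#' @param state_index Positive integer vector; 1 labels S1.
#' @param delta_e_ev Excitation energies in eV, > 0.
#' @param osc_strength Oscillator strengths, >= 0.
#' @param e_mo_initial_ev,e_mo_final_ev Optional MO energies in eV (`NA` when
#'   not available). When both are present the initiating orbital must lie
#'   below the receiving one.
#' @return A data frame with columns `state_index`, `delta_e_ev`,
#'   `osc_strength`, `e_mo_initial_ev`, `e_mo_final_ev`, sorted by state index.
#' @export
excitation_entry <- function(state_index, delta_e_ev, osc_strength,
                             e_mo_initial_ev = NA_real_,
                             e_mo_final_ev = NA_real_) {
  n <- length(state_index)
  df <- data.frame(
    state_index = as.integer(state_index),
    delta_e_ev = as.numeric(delta_e_ev),
    osc_strength = as.numeric(osc_strength),
    e_mo_initial_ev = rep_len(as.numeric(e_mo_initial_ev), n),
    e_mo_final_ev = rep_len(as.numeric(e_mo_final_ev), n)
  )
  df[order(df$state_index), , drop = FALSE]
}

#' Create a snapshot record
#'
#' @param snapshot_id Character identifier, unique within a record set.
#' @param time_ps Simulation time of the snapshot in ps, >= 0.
#' @param excitations Excitation table as returned by [excitation_entry()].
#' @param dihedrals Optional named numeric vector of dihedral angles in
#'   degrees, each in (-180, 180].
#' @param coeff_block_id Optional identifier of a sidecar LCAO coefficient
#'   block.
#' @return An object of class `snapshot_record`.
#' @export
snapshot_record <- function(snapshot_id, time_ps, excitations,
                            dihedrals = NULL, coeff_block_id = NULL) {
  rec <- structure(
    list(snapshot_id = as.character(snapshot_id),
         time_ps = as.numeric(time_ps),
         excitations = excitations,
         dihedrals = dihedrals,
         coeff_block_id = coeff_block_id),
    class = "snapshot_record")
  validate_snapshot_record(rec)
  rec
}

#' Validate a snapshot record against the data-model invariants
#'
#' Checks the excitation-table invariants (positive excitation energies,
#' non-negative oscillator strengths, unique sorted state indices, initiating
#' MO below receiving MO when both are present) and the dihedral range.
#'
#' @param rec A `snapshot_record`.
#' @return The record, invisibly; stops with an informative error naming the
#'   snapshot and offending field otherwise.
#' @export
validate_snapshot_record <- function(rec) {
  id <- rec$snapshot_id
  fail <- function(field, msg)
    stop(sprintf("snapshot '%s': invalid %s: %s", id, field, msg), call. = FALSE)
  if (!is.character(id) || length(id) != 1L || is.na(id))
    stop("snapshot_id must be a single string", call. = FALSE)
  if (!is.numeric(rec$time_ps) || length(rec$time_ps) != 1L ||
      !is.finite(rec$time_ps) || rec$time_ps < 0)
    fail("time_ps", "must be a single non-negative number")
  ex <- rec$excitations
  if (!is.data.frame(ex) || !all(EXCITATION_COLS %in% names(ex)))
    fail("excitations", paste("must be a data frame with columns",
                              paste(EXCITATION_COLS, collapse = ", ")))
  if (nrow(ex) > 0L) {
    if (any(is.na(ex$state_index)) || any(ex$state_index < 1L))
      fail("state_index", "must be positive integers")
    if (is.unsorted(ex$state_index, strictly = TRUE))
      fail("state_index", "must be strictly increasing (sorted, unique)")
    if (any(!is.finite(ex$delta_e_ev)) || any(ex$delta_e_ev <= 0))
      fail("delta_e_ev", "must be finite and > 0")
    if (any(!is.finite(ex$osc_strength)) || any(ex$osc_strength < 0))
      fail("osc_strength", "must be finite and >= 0")
    both <- !is.na(ex$e_mo_initial_ev) & !is.na(ex$e_mo_final_ev)
    if (any(both & ex$e_mo_initial_ev >= ex$e_mo_final_ev))
      fail("e_mo_initial_ev", "initiating MO must lie below the receiving MO")
  }
  if (!is.null(rec$dihedrals)) {
    d <- rec$dihedrals
    if (!is.numeric(d) || is.null(names(d)) || any(names(d) == ""))
      fail("dihedrals", "must be a named numeric vector")
    if (any(!is.finite(d)) || any(d <= -180) || any(d > 180))
      fail("dihedrals", "angles must lie in (-180, 180]")
  }
  invisible(rec)
}

#' @export
print.snapshot_record <- function(x, ...) {
  cat(sprintf("<snapshot_record> id=%s t=%.1f ps, %d excitation(s)%s\n",
              x$snapshot_id, x$time_ps, nrow(x$excitations),
              if (is.null(x$dihedrals)) "" else
                sprintf(", dihedrals: %s", paste(names(x$dihedrals), collapse = ", "))))
  invisible(x)
}

#' Flatten a record list into one excitation table
#'
#' Collects the excitations of all snapshots into a single data frame, the
#' form the spectrum builder and the MO-energy statistics consume.
#'
#' @param records List of `snapshot_record` objects.
#' @return Data frame with columns `snapshot_id`, `time_ps` and the excitation
#'   columns; zero rows for an empty list.
#' @export
excitation_table <- function(records) {
  if (length(records) == 0L)
    return(cbind(data.frame(snapshot_id = character(0), time_ps = numeric(0)),
                 excitation_entry(integer(0), numeric(0), numeric(0))))
  per <- vapply(records, function(r) nrow(r$excitations), integer(1))
  tab <- do.call(rbind, lapply(records, `[[`, "excitations"))
  tab$snapshot_id <- rep(vapply(records, `[[`, character(1), "snapshot_id"), per)
  tab$time_ps <- rep(vapply(records, `[[`, numeric(1), "time_ps"), per)
  rownames(tab) <- NULL
  tab[, c("snapshot_id", "time_ps", EXCITATION_COLS)]
}

#' Write snapshot records as JSON Lines
#'
#' One snapshot per line, in list order. The schema mirrors the in-memory
#' model: `snapshot_id`, `time_ps`, `excitations` (array of objects),
#' `dihedrals` (object or null), `coeff_block_id` (string or null).
#'
#' @param records List of valid `snapshot_record` objects.
#' @param path Output file path.
#' @return The number of records written, invisibly.
#' @export
write_snapshot_records <- function(records, path) {
  lines <- vapply(records, function(rec) {
    validate_snapshot_record(rec)
    ex <- rec$excitations
    obj <- list(
      snapshot_id = rec$snapshot_id,
      time_ps = rec$time_ps,
      excitations = lapply(seq_len(nrow(ex)), function(i) {
        e <- list(state_index = ex$state_index[i],
                  delta_e_ev = ex$delta_e_ev[i],
                  osc_strength = ex$osc_strength[i],
                  e_mo_initial_ev = ex$e_mo_initial_ev[i],
                  e_mo_final_ev = ex$e_mo_final_ev[i])
        e$e_mo_initial_ev <- if (is.na(e$e_mo_initial_ev)) NULL else e$e_mo_initial_ev
        e$e_mo_final_ev <- if (is.na(e$e_mo_final_ev)) NULL else e$e_mo_final_ev
        e
      }),
      dihedrals = if (is.null(rec$dihedrals)) NULL else as.list(rec$dihedrals),
      coeff_block_id = rec$coeff_block_id
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(length(records))
}

#' Read snapshot records from a JSON-Lines file
#'
#' Parses and validates the file written by [write_snapshot_records()]. File
#' order is preserved; every record is checked against the data-model
#' invariants and an invalid line raises an error naming the snapshot and the
#' offending field.
#'
#' @param path Path to a JSON-Lines record file.
#' @return List of `snapshot_record` objects (empty list for an empty file).
#' @export
read_snapshot_records <- function(path) {
  if (!file.exists(path)) stop("no such record file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("line %d: malformed JSON: %s", i, conditionMessage(e)),
                           call. = FALSE))
    for (f in c("snapshot_id", "time_ps", "excitations"))
      if (is.null(obj[[f]]))
        stop(sprintf("line %d: missing required field '%s'", i, f), call. = FALSE)
    ex <- obj$excitations
    num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    tab <- excitation_entry(
      state_index = vapply(ex, function(e) as.integer(e$state_index), integer(1)),
      delta_e_ev = vapply(ex, function(e) num_or_na(e$delta_e_ev), numeric(1)),
      osc_strength = vapply(ex, function(e) num_or_na(e$osc_strength), numeric(1)),
      e_mo_initial_ev = vapply(ex, function(e) num_or_na(e$e_mo_initial_ev), numeric(1)),
      e_mo_final_ev = vapply(ex, function(e) num_or_na(e$e_mo_final_ev), numeric(1))
    )
    dih <- if (is.null(obj$dihedrals)) NULL else unlist(obj$dihedrals)
    snapshot_record(obj$snapshot_id, obj$time_ps, tab,
                    dihedrals = dih, coeff_block_id = obj$coeff_block_id)
  })
}

#' Number of snapshots sampled from a production run
#'
#' Snapshots are taken on the grid t = interval, 2 interval, ..., duration
#' (t = 0 excluded), so a 10 ns run sampled every 10 ps yields 1000 snapshots
#' and a 30 ns run yields 3000.
#'
#' @param duration_ps Production length in ps, > 0.
#' @param interval_ps Sampling interval in ps, > 0; must divide the duration
#'   (within a 1e-9 relative tolerance).
#' @return Integer snapshot count, floor(duration / interval).
#' @export
sample_count <- function(duration_ps, interval_ps) {
  if (!is.numeric(duration_ps) || length(duration_ps) != 1L || duration_ps <= 0)
    stop("duration_ps must be a single positive number")
  if (!is.numeric(interval_ps) || length(interval_ps) != 1L || interval_ps <= 0)
    stop("interval_ps must be a single positive number")
  ratio <- duration_ps / interval_ps
  if (abs(ratio - round(ratio)) > 1e-9 * max(1, ratio))
    stop("duration_ps must be an integer multiple of interval_ps")
  as.integer(floor(ratio + 0.5))
}
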