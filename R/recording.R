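#' Construct a grid-cell recording
#'
#' A recording bundles one foraging session: the sampled 2-D trajectory, one
#' spike-time train per unit, the arena size, and opaque module/session
#' labels. Coordinates are continuous centimetres with the origin at an
#' arena corner, so every position lies in `[0, Lx] x [0, Ly]`.
#'
#' Each position sample carries a dwell time: the interval to the next
#' sample (the last sample gets the median interval). Dwells are computed on
#' the full trajectory and preserved when a recording is subset to temporal
#' bins, so occupancy stays conserved across split halves.
#'
#' @param positions Data frame with columns `t` (s, strictly increasing),
#'   `x`, `y` (cm) and optionally `dwell` (s).
#' @param spikes Named list of numeric spike-time vectors (s), one per unit.
#' @param arena Length-2 numeric `c(Lx, Ly)` in cm.
#' @param module_id,session_id Opaque labels.
#'
#' @return An object of class `"grid_recording"`.
#' @export
#' @examples
#' pos <- data.frame(t = seq(0, 1, 0.1), x = 10, y = 10)
#' rec <- grid_recording(pos, list(u1 = c(0.25, 0.5)), arena = c(150, 150))
#' rec
grid_recording <- function(positions, spikes, arena = c(150, 150),
                           module_id = "m1", session_id = "s1") {
  positions <- as_tibble(positions)
  stopifnot(all(c("t", "x", "y") %in% names(positions)),
            nrow(positions) >= 2)
  if (any(diff(positions$t) <= 0)) {
    abort("position timestamps must be strictly increasing")
  }
  if (any(positions$x < 0 - 1e-9 | positions$x > arena[1] + 1e-9 |
          positions$y < 0 - 1e-9 | positions$y > arena[2] + 1e-9)) {
    abort("positions fall outside the arena [0, Lx] x [0, Ly]")
  }
  if (!("dwell" %in% names(positions))) {
    dt <- diff(positions$t)
    positions$dwell <- c(dt, median(dt))
  }
  if (is.null(names(spikes))) {
    names(spikes) <- paste0("u", seq_along(spikes))
  }
  t0 <- positions$t[1]
  t1 <- positions$t[nrow(positions)]
  for (u in names(spikes)) {
    st <- spikes[[u]]
    if (length(st) && (min(st) < t0 - 1e-9 || max(st) > t1 + 1e-9)) {
      abort(sprintf("unit '%s' has spikes outside the trajectory span", u))
    }
    spikes[[u]] <- sort(as.numeric(st))
  }
  structure(
    list(positions = positions, spikes = spikes,
         arena = as.numeric(arena), unit_ids = names(spikes),
         module_id = module_id, session_id = session_id),
    class = "grid_recording"
  )
}

#' @export
print.grid_recording <- function(x, ...) {
  dur <- diff(range(x$positions$t)) / 60
  cat(sprintf(
    "<grid_recording> session %s, module %s: %d units, %.1f min, %g x %g cm arena\n",
    x$session_id, x$module_id, length(x$spikes), dur, x$arena[1], x$arena[2]))
  nsp <- vapply(x$spikes, length, integer(1))
  if (any(nsp == 0)) {
    cat(sprintf("  note: %d unit(s) with zero spikes\n", sum(nsp == 0)))
  }
  invisible(x)
}

#' Total duration (s) of a recording, as the sum of per-sample dwell times.
#' @param rec A [grid_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) sum(rec$positions$dwell)

#' Load a recording from a session directory
#'
#' Reads the flat on-disk session layout: `positions.csv` with columns
#' `t,x,y`, one `spikes/<unit_id>.csv` (single column `t`) per unit, and
#' `meta.json` holding the arena size, module/session labels and the unit
#' order. Units with zero spikes are retained. The same layout is written by
#' [save_recording()] and by the synthetic generator, and is the documented
#' target for converters from archival deposits.
#'
#' @param path Session directory.
#' @return A validated [grid_recording()]; unit order follows `meta.json`.
#' @export
load_recording <- function(path) {
  pos_file <- file.path(path, "positions.csv")
  meta_file <- file.path(path, "meta.json")
  for (f in c(pos_file, meta_file)) {
    if (!file.exists(f)) abort(sprintf("missing session component: %s", f))
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  positions <- read.csv(pos_file)
  spikes <- lapply(meta$unit_ids, function(u) {
    f <- file.path(path, "spikes", paste0(u, ".csv"))
    if (!file.exists(f)) abort(sprintf("missing session component: %s", f))
    df <- read.csv(f)
    if (nrow(df) == 0) numeric(0) else as.numeric(df$t)
  })
  names(spikes) <- meta$unit_ids
  grid_recording(positions, spikes, arena = as.numeric(meta$arena),
                 module_id = meta$module_id %||% "m1",
                 session_id = meta$session_id %||% basename(path))
}

#' Save a recording as a session directory
#'
#' Writes the flat layout read by [load_recording()]. Numeric columns are
#' written with full double precision so that a save/load round trip is
#' value-exact.
#'
#' @param rec A [grid_recording()].
#' @param path Session directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  dir.create(file.path(path, "spikes"), recursive = TRUE, showWarnings = FALSE)
  pos <- as.data.frame(rec$positions[, c("t", "x", "y")])
  write.csv(format(pos, digits = 17, trim = TRUE, scientific = FALSE),
            file.path(path, "positions.csv"), row.names = FALSE, quote = FALSE)
  for (u in rec$unit_ids) {
    df <- data.frame(t = rec$spikes[[u]])
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              file.path(path, "spikes", paste0(u, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(arena = rec$arena, module_id = rec$module_id,
         session_id = rec$session_id, unit_ids = rec$unit_ids),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save a result table with a reproducibility sidecar
#'
#' Writes any result tibble (per-cell variability table, decoding sweep,
#' ...) as CSV plus a JSON sidecar recording the configuration, seed and
#' package version needed for an exact rerun.
#'
#' @param tbl A data frame.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @param config Optional [grid_config()] echoed into the sidecar.
#' @param seed Optional seed echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
save_results <- function(tbl, path, config = NULL, seed = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  df <- as.data.frame(tbl)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 15))
  write.csv(df, path, row.names = FALSE)
  sidecar <- list(
    package = "gridvar",
    version = as.character(utils::packageVersion("gridvar")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    n_rows = nrow(df),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Restrict a recording to a set of temporal bins (internal; used by the
# split-half analysis). `bins` is a two-column matrix of [start, end) times.
# Per-sample dwells from the full trajectory are preserved.
subset_recording_time <- function(rec, bins) {
  t <- rec$positions$t
  keep <- rep(FALSE, length(t))
  for (i in seq_len(nrow(bins))) {
    keep <- keep | (t >= bins[i, 1] & t < bins[i, 2])
  }
  pos <- rec$positions[keep, , drop = FALSE]
  spikes <- lapply(rec$spikes, function(st) {
    if (!length(st)) return(numeric(0))
    k <- rep(FALSE, length(st))
    for (i in seq_len(nrow(bins))) {
      k <- k | (st >= bins[i, 1] & st < bins[i, 2])
    }
    st[k]
  })
  out <- rec
  out$positions <- pos
  out$spikes <- spikes
  out
}
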