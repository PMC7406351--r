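#' Echolocation phase parameter table
#'
#' Anchor values of the echolocation parameters over the hunting phases of an
#' FM bat (Pipistrellus kuhlii repertoire, first harmonic). Within the
#' approach and first buzz stage the inter-pulse interval (IPI), call
#' duration, bandwidth and source level interpolate linearly in distance
#' between the start and end anchors; terminal frequency drops to 19 kHz only
#' in the final buzz.
#'
#' @return A data frame with one row per anchor (search, approach start/end,
#'   buzz-I start/end, buzz-II) and columns `dist_m`, `ipi_ms`, `dur_ms`,
#'   `tf_khz`, `bw_khz`, `sl_db`.
#' @export
echolocation_phase_table <- function() {
  data.frame(
    anchor = c("search", "approach_start", "approach_end",
               "buzz1_start", "buzz1_end", "buzz2"),
    dist_m = c(Inf, 1.2, 0.4, 0.4, 0.2, 0.2),
    ipi_ms = c(100, 70, 35, 18, 6, 5),
    dur_ms = c(7, 5, 2, 2, 1, 0.5),
    tf_khz = c(39, 39, 39, 39, 39, 19),
    bw_khz = c(8, 35, 30, 30, 20, 20),
    sl_db  = c(110, 110, 90, 90, 80, 80),
    stringsAsFactors = FALSE
  )
}

#' Phase and call parameters for a given distance to target
#'
#' Maps the (estimated) distance to the pursued target onto the hunting phase
#' and its call parameters. No target or distance > 1.2 m gives the search
#' row; 1.2-0.4 m interpolates the approach anchors linearly; 0.4-0.2 m
#' interpolates the buzz-I anchors; below 0.2 m the buzz-II row applies.
#'
#' @param distance Distance to the pursued target in metres, or `NULL`/`NA`
#'   when no target is detected. Negative distances are an error.
#' @param tf_offset_khz Individual terminal-frequency offset in kHz (the
#'   whole call band shifts with the terminal frequency; bandwidth is
#'   unchanged).
#' @param sl_offset_db Offset applied to the source-level column (used for
#'   source-level sweeps; 0 keeps the table's 110 dB-SPL search level).
#' @param search_dur_ms Search-call duration override in ms (call-duration
#'   experiment); the approach/buzz anchors are unchanged.
#' @return A list with `phase` (one of `"search"`, `"approach"`, `"buzz1"`,
#'   `"buzz2"`), `ipi_s`, `dur_ms`, `tf_khz`, `bw_khz`, `sl_db`.
#' @export
phase_and_call_params <- function(distance = NULL, tf_offset_khz = 0,
                                  sl_offset_db = 0, search_dur_ms = NULL) {
  # rows: search, approach_start, approach_end, buzz1_start, buzz1_end, buzz2
  # cols: ipi_ms, dur_ms, tf_khz, bw_khz, sl_db (values of Table anchors)
  M <- .phase_anchor_matrix
  if (!is.null(search_dur_ms)) M[1, 2] <- search_dur_ms
  if (is.null(distance) || is.na(distance)) distance <- Inf
  if (distance < 0) stop("distance to target must be non-negative")
  if (distance > 1.2) {
    phase <- "search"; v <- M[1, ]
  } else if (distance > 0.4) {
    w <- (1.2 - distance) / 0.8
    phase <- "approach"; v <- M[2, ] * (1 - w) + M[3, ] * w
  } else if (distance > 0.2) {
    w <- (0.4 - distance) / 0.2
    phase <- "buzz1"; v <- M[4, ] * (1 - w) + M[5, ] * w
  } else {
    phase <- "buzz2"; v <- M[6, ]
  }
  list(phase = phase,
       ipi_s = v[[1]] / 1000,
       dur_ms = v[[2]],
       tf_khz = v[[3]] + tf_offset_khz,
       bw_khz = v[[4]],
       sl_db = v[[5]] + sl_offset_db)
}

.phase_anchor_matrix <- matrix(
  c(100, 7,   39, 8,  110,
    70,  5,   39, 35, 110,
    35,  2,   39, 30, 90,
    18,  2,   39, 30, 90,
    6,   1,   39, 20, 80,
    5,   0.5, 19, 20, 80),
  nrow = 6, byrow = TRUE,
  dimnames = list(NULL, c("ipi_ms", "dur_ms", "tf_khz", "bw_khz", "sl_db")))
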