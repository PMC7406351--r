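#' Assign per-bat terminal frequencies
#'
#' Three frequency-assignment regimes are supported: `"identical"` gives every
#' bat the repertoire terminal frequency of 39 kHz; `"random"` draws each
#' bat's search-phase terminal frequency from N(39, 4) kHz, matching the
#' between-individual variance observed in the field; `"jar"` draws like
#' `"random"` but the bats will additionally shift their band away from
#' maskers (see [jar_update()]), so the draws are truncated to the JAR bounds
#' \[35, 43\] kHz. The whole call band shifts with the terminal frequency; the
#' bandwidth is unchanged.
#'
#' @param n_bats Number of bats (>= 1).
#' @param regime One of `"identical"`, `"random"`, `"jar"`.
#' @return Numeric vector of search-phase terminal frequencies in kHz.
#' @export
assign_terminal_frequencies <- function(n_bats,
                                        regime = c("identical", "random", "jar")) {
  if (!is.numeric(n_bats) || n_bats < 1) stop("n_bats must be >= 1")
  regime <- match.arg(regime)
  switch(regime,
    identical = rep(39, n_bats),
    random = stats::rnorm(n_bats, 39, 4),
    jar = pmin(pmax(stats::rnorm(n_bats, 39, 4), 35), 43)
  )
}

#' Spectral jamming avoidance response update
#'
#' When the echo of the pursued prey is jammed, the bat shifts its entire
#' call band 2 kHz away from the masker's terminal frequency (masker lower ->
#' shift up; masker higher -> shift down; exact tie -> up, matching the
#' upward shifts reported in playback studies). The terminal frequency is
#' clamped to \[35, 43\] kHz. The shifted repertoire is kept for five
#' consecutive calls, tracked by a hold counter; a further jam during the
#' hold shifts again and resets the counter. After the hold expires without a
#' jam the frequency stays at its shifted value.
#'
#' @param tf_khz Current search-phase terminal frequency (kHz).
#' @param jammed Logical: was the pursued prey's echo jammed on this call?
#' @param masker_tf_khz Terminal frequency of the jamming masker (kHz);
#'   ignored when `jammed` is `FALSE`.
#' @param hold Current hold counter (calls remaining).
#' @param step_khz Shift step (default 2 kHz).
#' @param bounds Terminal-frequency bounds in kHz (default `c(35, 43)`).
#' @return List with updated `tf_khz` and `hold`.
#' @export
jar_update <- function(tf_khz, jammed, masker_tf_khz = NA, hold = 0,
                       step_khz = 2, bounds = c(35, 43)) {
  if (isTRUE(jammed)) {
    dir <- if (!is.na(masker_tf_khz) && masker_tf_khz > tf_khz) -1 else 1
    tf_khz <- min(max(tf_khz + dir * step_khz, bounds[1]), bounds[2])
    hold <- 5
  } else {
    hold <- max(0L, hold - 1L)
  }
  list(tf_khz = tf_khz, hold = hold)
}
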