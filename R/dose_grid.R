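#' Default warfarin dose grid
#'
#' The 16 candidate daily doses (mg) considered when inverting the INR
#' predictor.  Marketed warfarin tablets are 2.5 mg and 3 mg and are split
#' into quarters, so the grid is the union of quarter-tablet multiples of
#' 2.5 mg (1..9 quarters) and of 3 mg (1..8 quarters), deduplicated
#' (3.75 mg arises from both).
#'
#' @return Strictly increasing numeric vector of 16 doses in mg/day.
#' @examples
#' default_dose_grid()
#' @export
default_dose_grid <- function() {
  grid <- sort(unique(c((1:9) * 2.5 / 4, (1:8) * 3 / 4)))
  stopifnot(length(grid) == 16L)
  grid
}
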