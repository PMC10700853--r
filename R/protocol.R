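#' Build a three-segment temperature protocol
#'
#' Constructs the canonical chilling protocol used throughout: a warm
#' pre-recording segment at 35 degC, a cold segment at `cold_temp_C`, and a
#' rewarmed segment back at 35 degC. Degenerate protocols (zero-length
#' segments) are allowed as long as the total duration is positive, so a
#' constant-temperature recording is `build_protocol(0, 35, 0, total_h)`.
#'
#' @param pre_h Hours at 35 degC before chilling.
#' @param cold_temp_C Temperature of the cold segment, degC (5--40).
#' @param cold_h Duration of the cold segment, hours.
#' @param post_h Hours at 35 degC after rewarming.
#' @param warm_temp_C Temperature of the warm segments, degC. Default 35.
#'
#' @return A `temperature_protocol`: a tibble with columns `start_h` and
#'   `temp_C` (one row per segment, zero-length segments dropped) and an
#'   attribute `total_h`.
#' @examples
#' build_protocol(96, 15, 96, 96)   # 4 d warm / 4 d at 15 degC / 4 d rewarmed
#' build_protocol(0, 35, 0, 288)    # constant 35 degC, 12 days
#' @export
build_protocol <- function(pre_h, cold_temp_C, cold_h, post_h, warm_temp_C = 35) {
  stopifnot(is.numeric(pre_h), is.numeric(cold_h), is.numeric(post_h),
            is.numeric(cold_temp_C), length(cold_temp_C) == 1L)
  if (any(c(pre_h, cold_h, post_h) < 0)) {
    stop("segment durations must be non-negative", call. = FALSE)
  }
  total_h <- pre_h + cold_h + post_h
  if (total_h <= 0) stop("protocol must have positive total duration", call. = FALSE)
  seg <- tibble::tibble(
    start_h = c(0, pre_h, pre_h + cold_h),
    temp_C  = c(warm_temp_C, cold_temp_C, warm_temp_C),
    len_h   = c(pre_h, cold_h, post_h)
  )
  seg <- seg[seg$len_h > 0, c("start_h", "temp_C")]
  # merge adjacent segments at identical temperature
  keep <- c(TRUE, diff(seg$temp_C) != 0)
  seg <- seg[keep, ]
  seg$start_h[1] <- 0
  new_protocol(seg, total_h)
}

new_protocol <- function(segments, total_h) {
  stopifnot(all(diff(segments$start_h) > 0), segments$start_h[1] == 0,
            all(segments$start_h < total_h),
            all(segments$temp_C >= 5 & segments$temp_C <= 40))
  structure(segments,
            total_h = total_h,
            class = c("temperature_protocol", class(tibble::tibble())))
}

#' Construct a temperature protocol from explicit segments
#'
#' @param start_h Numeric vector of segment start times (hours); must begin
#'   at 0 and be strictly increasing.
#' @param temp_C Numeric vector of segment temperatures (degC, 5--40).
#' @param total_h Total recording duration, hours.
#' @return A `temperature_protocol` tibble.
#' @export
temperature_protocol <- function(start_h, temp_C, total_h) {
  stopifnot(length(start_h) == length(temp_C), length(start_h) >= 1L)
  new_protocol(tibble::tibble(start_h = as.numeric(start_h),
                              temp_C = as.numeric(temp_C)), total_h)
}

#' Temperature at given times under a protocol
#'
#' Piecewise-constant lookup: each sample takes the temperature of the
#' protocol segment covering it.
#'
#' @param protocol A `temperature_protocol`.
#' @param time_h Numeric vector of times in hours, within `[0, total_h]`.
#' @return Numeric vector of temperatures, degC.
#' @export
protocol_temperature <- function(protocol, time_h) {
  stopifnot(inherits(protocol, "temperature_protocol"))
  total_h <- attr(protocol, "total_h")
  if (any(time_h < 0 | time_h > total_h)) {
    stop("time_h outside protocol range [0, ", total_h, "]", call. = FALSE)
  }
  idx <- findInterval(time_h, protocol$start_h)
  protocol$temp_C[idx]
}

#' @export
print.temperature_protocol <- function(x, ...) {
  cat("<temperature_protocol> total ", attr(x, "total_h"), " h\n", sep = "")
  NextMethod()
  invisible(x)
}
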