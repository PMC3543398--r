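# Individual recovery models: f(t) = a + b*ln(t) (logarithmic) and
# f(t) = a + b*t (linear), with t in integer days since stroke onset.

MMSE_MIN <- 0L
MMSE_MAX <- 30L

#' Recovery model for a bounded cognitive score
#'
#' Represents an early-phase recovery curve for the Mini-Mental State
#' Examination (MMSE, 0--30 points) as a function of days since stroke
#' onset `t`: either `a + b * ln(t)` (`kind = "logarithmic"`) or
#' `a + b * t` (`kind = "linear"`).
#'
#' The intercept `a` is the model value at the time origin of the
#' transformed axis: for the logarithmic model this is the score at
#' day 1 (not day 0, where `ln` is undefined); for the linear model it
#' is the extrapolated score at day 0. The slope `b` is the rate of
#' early-phase recovery in points per unit of transformed time
#' (points per ln-day, or points per day). A negative `b` encodes
#' cognitive decline and is permitted.
#'
#' @param kind `"logarithmic"` or `"linear"`.
#' @param a Intercept, MMSE points (finite real).
#' @param b Slope, points per unit of transformed time (finite real).
#' @return An object of class `recovery_model`: a list with elements
#'   `kind`, `a`, `b`.
#' @seealso [fit_two_point()], [predict.recovery_model()]
#' @examples
#' m <- recovery_model("logarithmic", a = 20, b = 3)
#' predict(m, day = c(5, 12, 19, 26))
#' @export
recovery_model <- function(kind = c("logarithmic", "linear"), a, b) {
  kind <- match.arg(kind)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("intercept 'a' must be a single finite number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("slope 'b' must be a single finite number", call. = FALSE)
  structure(list(kind = kind, a = as.numeric(a), b = as.numeric(b)),
            class = "recovery_model")
}

#' @export
print.recovery_model <- function(x, ...) {
  form <- if (x$kind == "logarithmic") "a + b*ln(t)" else "a + b*t"
  cat(sprintf("<recovery_model> %s: %s\n  a = %.6g points, b = %.6g points per %s\n",
              x$kind, form, x$a, x$b,
              if (x$kind == "logarithmic") "ln(day)" else "day"))
  invisible(x)
}

time_transform <- function(day, kind) {
  if (kind == "logarithmic") log(day) else as.numeric(day)
}

check_days <- function(day, kind = "logarithmic", what = "day") {
  if (!is.numeric(day) || any(!is.finite(day)))
    stop(sprintf("'%s' must be finite numeric", what), call. = FALSE)
  if (any(day < 1))
    stop(sprintf("'%s' must be >= 1 (days are counted from stroke onset; %s)",
                 what,
                 if (kind == "logarithmic") "ln(t) is undefined below day 1"
                 else "a same-day assessment is encoded as day 1"),
         call. = FALSE)
  invisible(day)
}

#' Tailor a recovery model exactly through two early assessments
#'
#' Solves the two-parameter recovery curve that passes exactly through
#' two anchor assessments of the same patient, the individualization
#' step of the two-point prognosis method. The score change between
#' the anchors (delta MMSE) determines the slope:
#' `b = delta / (ln(day2) - ln(day1))` for the logarithmic model and
#' `b = delta / (day2 - day1)` for the linear model; the intercept is
#' then solved so that the curve reproduces the first anchor.
#'
#' Any pair of distinct early assessment days is a valid anchor pair;
#' a negative delta (declining patient) yields a negative slope and is
#' not rejected.
#'
#' @param day Integer vector of length 2, strictly increasing days
#'   since stroke onset (both >= 1).
#' @param score Numeric vector of length 2, MMSE points at those days.
#' @param kind `"logarithmic"` or `"linear"`.
#' @return A [recovery_model()].
#' @examples
#' fit_two_point(c(5, 12), c(20, 24), "logarithmic")
#' fit_two_point(c(5, 12), c(20, 24), "linear")
#' @export
fit_two_point <- function(day, score, kind = c("logarithmic", "linear")) {
  kind <- match.arg(kind)
  if (length(day) != 2L || length(score) != 2L)
    stop("exactly two anchor assessments (day, score) are required", call. = FALSE)
  if (!is.numeric(score) || any(!is.finite(score)))
    stop("anchor scores must be finite numeric", call. = FALSE)
  check_days(day, kind)
  if (day[1L] == day[2L])
    stop("degenerate anchors: both assessments fall on day ", day[1L],
         "; two distinct days are required", call. = FALSE)
  if (day[1L] > day[2L])
    stop("anchor days must be strictly increasing", call. = FALSE)
  tt <- time_transform(day, kind)
  b <- (score[2L] - score[1L]) / (tt[2L] - tt[1L])
  a <- score[1L] - b * tt[1L]
  recovery_model(kind, a, b)
}

#' Change in MMSE score between two assessments
#'
#' The score increase between two anchor assessments (second minus
#' first), the basis of the tailored slope. May be negative for a
#' declining patient.
#'
#' @inheritParams fit_two_point
#' @return Single numeric, `score[2] - score[1]`.
#' @export
delta_mmse <- function(day, score) {
  if (length(day) != 2L || length(score) != 2L)
    stop("exactly two assessments (day, score) are required", call. = FALSE)
  if (day[1L] >= day[2L])
    stop("anchor days must be strictly increasing", call. = FALSE)
  score[2L] - score[1L]
}

#' Predict MMSE scores from a recovery model
#'
#' Evaluates the fitted curve at forecast days. Predictions are real
#' numbers by default; `clamp` truncates them into the instrument
#' range 0--30 (ceiling and floor effects of the MMSE), and
#' `round_score` rounds to whole points for display.
#'
#' @param object A [recovery_model()].
#' @param day Forecast days since onset (numeric, all >= 1).
#' @param clamp If `TRUE`, truncate predictions into `[0, 30]`.
#' @param round_score If `TRUE`, round to integer points (applied
#'   after clamping).
#' @param ... Unused.
#' @return Numeric vector of predicted MMSE points.
#' @export
predict.recovery_model <- function(object, day, clamp = FALSE,
                                   round_score = FALSE, ...) {
  check_days(day, object$kind)
  out <- object$a + object$b * time_transform(day, object$kind)
  if (clamp) out <- pmin(MMSE_MAX, pmax(MMSE_MIN, out))
  if (round_score) out <- round(out)
  out
}

#' Serialize / deserialize a recovery model as JSON
#'
#' A model is stored as the record `{"kind": ..., "a": ..., "b": ...}`.
#'
#' @param model A [recovery_model()].
#' @param txt A JSON string as produced by `model_to_json()`.
#' @return `model_to_json()` returns a JSON string;
#'   `model_from_json()` returns a [recovery_model()].
#' @export
model_to_json <- function(model) {
  stopifnot(inherits(model, "recovery_model"))
  as.character(jsonlite::toJSON(unclass(model), auto_unbox = TRUE, digits = NA))
}

#' @rdname model_to_json
#' @export
model_from_json <- function(txt) {
  rec <- jsonlite::fromJSON(txt)
  recovery_model(rec$kind, rec$a, rec$b)
}
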