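#' Map an apnea-hypopnea index to a severity class
#'
#' Applies the clinical AHI cut-offs: below 5 events/h is `non`,
#' 5 to <15 `mild`, 15 to <30 `moderate`, and 30 or more `severe`.
#' Intervals are left-closed.
#'
#' @param ahi numeric vector of AHI values (events/hour), non-negative
#' @return Character vector of severity labels (see [severityLevels()]).
#' @examples
#' severityFromAhi(c(1.18, 5, 14.9, 30))
#' @export
severityFromAhi <- function(ahi) {
  if (!is.numeric(ahi) || any(is.na(ahi)) || any(ahi < 0))
    stop("ahi must be non-negative and non-missing")
  cut(ahi, breaks = c(-Inf, 5, 15, 30, Inf), right = FALSE,
      labels = severityLevels()) |> as.character()
}

#' Class schemes for the meta-model
#'
#' The four-class scheme keeps all severity labels; the three-class scheme
#' merges `moderate` and `severe` into `moderate_severe`.
#'
#' @param name `"three"` or `"four"`
#' @return A list with `name`, ordered `classes`, and `merge_map`
#'   (raw severity -> scheme class).
#' @export
classScheme <- function(name = c("four", "three")) {
  name <- match.arg(name)
  raw <- severityLevels()
  if (name == "four") {
    list(name = "four", classes = raw,
         merge_map = stats::setNames(raw, raw))
  } else {
    list(name = "three", classes = c("non", "mild", "moderate_severe"),
         merge_map = stats::setNames(c("non", "mild", "moderate_severe", "moderate_severe"), raw))
  }
}

#' Map raw severity labels through a class scheme
#' @param severity character vector of raw severity labels
#' @param scheme a scheme from [classScheme()]
#' @return Character vector of scheme classes.
#' @export
applyScheme <- function(severity, scheme) {
  unname(scheme$merge_map[severity])
}
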