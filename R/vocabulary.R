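#' State vocabulary with a reserved RESET symbol
#'
#' An ordered set of distinct state labels plus a reserved boundary symbol
#' (RESET) that is guaranteed not to occur in the data.  The total state
#' count `m` includes RESET, so `m = length(labels) + 1`.
#'
#' @param labels Character vector of distinct state labels (data states).
#' @param reset_label Reserved boundary label; must not occur in `labels`.
#'   If `NULL`, a non-colliding label is generated (`"RESET"`, `"RESET."`,
#'   ... until free).
#'
#' @return An object of class `state_vocabulary` with fields `labels`,
#'   `reset_label` and `m`.
#' @export
#' @examples
#' v <- state_vocabulary(c("A", "B", "C"))
#' v$m  # 4
state_vocabulary <- function(labels, reset_label = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("state labels must be unique")
  if (length(labels) < 1L) stop("vocabulary needs at least one label")
  if (is.null(reset_label)) {
    reset_label <- "RESET"
    while (reset_label %in% labels) reset_label <- paste0(reset_label, ".")
  } else {
    reset_label <- as.character(reset_label)
    if (reset_label %in% labels) {
      stop("reserved label in data: ", reset_label)
    }
  }
  structure(
    list(labels = labels, reset_label = reset_label,
         m = length(labels) + 1L),
    class = "state_vocabulary"
  )
}

#' @export
print.state_vocabulary <- function(x, ...) {
  cat("<state_vocabulary> ", length(x$labels), " labels + RESET ('",
      x$reset_label, "'), m = ", x$m, "\n", sep = "")
  invisible(x)
}

# Full state set in internal index order: data labels 1..m-1, RESET = m.
vocab_states <- function(vocab) c(vocab$labels, vocab$reset_label)

# Map labels to internal integer indices (RESET = m); error on unknowns.
vocab_index <- function(vocab, x) {
  i <- match(x, vocab_states(vocab))
  if (anyNA(i)) {
    stop("unknown state label(s): ",
         paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i
}
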