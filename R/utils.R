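# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# The three class labels of the classification problem. State labels may carry
# a detail tag after a colon, e.g. "pain:CFA" or "analgesic:morphine".
PAIN_CLASSES <- c("non-pain", "pain", "analgesic")

#' Class labels used by the classifier
#'
#' @return Character vector `c("non-pain", "pain", "analgesic")`.
#' @export
pain_classes <- function() PAIN_CLASSES

# Map a state label (possibly "class:detail") to its class.
state_class <- function(state_label) {
  cls <- sub(":.*$", "", state_label)
  bad <- !cls %in% PAIN_CLASSES
  if (any(bad)) {
    stop("invalid state label(s): ", paste(unique(state_label[bad]), collapse = ", "),
         "; expected one of ", paste(PAIN_CLASSES, collapse = ", "),
         " optionally followed by ':<detail>'", call. = FALSE)
  }
  cls
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic integer seed from a string (polynomial hash mod a prime).
string_seed <- function(x) {
  h <- 0
  for (i in utf8ToInt(x)) h <- (h * 31 + i) %% 2147483629
  as.integer(h)
}

# Fan a root seed out into per-stage / per-fold seeds, staying below 2^31.
make_seed <- function(root, salt) {
  as.integer((as.numeric(root) %% 65521 * 48271 + as.numeric(salt) * 16807 + 12345) %% 2147483647)
}

stop_classed <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "painstate_error")))
}
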