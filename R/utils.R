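# Internal helpers shared across modules.

invlogit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample skewness (unbiased-ish b1 form; only the sign is ever asserted).
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  mean((x - m)^3) / s^3
}

stop_frailty <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "frailtytrials_error")))
}

# female = 1, male = 0; accepts 0/1, logicals, or common string codings.
encode_sex <- function(sex) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) {
      stop_frailty("numeric sex codes must be 0 (male) / 1 (female)", class = "data_error")
    }
    return(as.numeric(sex))
  }
  if (is.logical(sex)) return(as.numeric(sex))
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("f", "female", "woman", "w"), 1,
         ifelse(s %in% c("m", "male", "man"), 0, NA_real_))
  if (anyNA(out)) {
    stop_frailty("unrecognised sex codes: %s",
                 paste(unique(sex[is.na(out)]), collapse = ", "),
                 class = "data_error")
  }
  out
}
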