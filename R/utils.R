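# internal helpers

.validationError <- function(msg, ...) {
  stop(errorCondition(msg, ...,
                      class = c("twoStepValidationError", "validationError")))
}

# deterministic sub-seed derivation; kept well below 2^31
.deriveSeed <- function(base, ...) {
  offs <- c(...)
  mix <- as.numeric(base)
  for (i in seq_along(offs))
    mix <- (mix * 48271 + offs[i] * 131 + i) %% 2147483629
  as.integer(mix) + 1L
}

.withSeed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# modal value; deterministic tie-break towards the smaller value
.modalValue <- function(x) {
  if (!length(x)) return(NA_real_)
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}

.patternKeys <- function(presence) {
  if (ncol(presence) == 0L) return(rep("", nrow(presence)))
  apply(presence, 1L, function(r) paste0(as.integer(r), collapse = ""))
}
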