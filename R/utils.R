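# Deterministic 31-bit seed derived from a master seed and arbitrary labels
# (level, replicate, method, ...). Polynomial rolling hash over the UTF-8
# bytes of the components; platform-independent, always in [1, 2^31 - 2] so
# it is a valid set.seed() input on 32-bit integer builds.
derive_seed <- function(master, ...) {
  parts <- vapply(list(master, ...), function(x) paste(format(x), collapse = ","),
                  character(1))
  bytes <- utf8ToInt(paste(parts, collapse = "|"))
  h <- 0
  m <- 2147483587  # prime below 2^31
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h + 1)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
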