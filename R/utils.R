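# Internal helpers: deterministic seed derivation and argument checks.

# data.table is used via :: only; this flag lets its [ method see our calls
.datatable.aware <- TRUE

# Derive a 31-bit seed from a master seed plus an arbitrary sequence of
# integer / numeric / character tags. Pure integer arithmetic on doubles
# (all intermediates < 2^53, so exact); the same tags always yield the same
# seed, independently of execution order -- this is what makes per-cell and
# per-replicate streams reproducible in isolation.
derive_seed <- function(...) {
  m <- 2147483629 # prime < 2^31
  h <- 17
  for (part in list(...)) {
    if (is.character(part)) {
      part <- unlist(lapply(part, utf8ToInt), use.names = FALSE)
    } else {
      # quarter-step betas etc. become exact integers after scaling
      part <- round(as.numeric(part) * 4096)
    }
    for (v in part) {
      h <- (h * 69069 + (v %% m) + 1) %% m
    }
  }
  as.integer(h)
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("interactsim_domain_error",
                                             "error", "condition")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("interactsim_config_error",
                                             "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_domain(name, " must be a single finite number")
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_domain(name, " = ", format(x), " is outside ",
                if (open_lower) "(" else "[", lower, ", ", upper,
                if (open_upper) ")" else "]")
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_domain(name, " must be TRUE or FALSE")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
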