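# internal helpers shared across modules

# Run `code` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps results below .Machine$integer.max so they remain valid R seeds.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483587)
}

stop_input <- function(...) {
  stop(structure(class = c("filmhnn_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# canonical order of the ten network input features
hnn_feature_names <- function() {
  c("r_nod",
    "r_ipv", "r_bpv",
    "g_ipv", "g_bpv",
    "b_ipv", "b_bpv",
    "r_it", "g_it", "b_it")
}
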