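# internal validation + misc helpers

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be TRUE or FALSE", name)
  x
}

.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    .stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

.check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    .stopf("'%s' must be a single number in [%s, %s]", name, min, max)
  as.numeric(x)
}

# derive a stage-specific 31-bit seed from a global seed and a label,
# so every pipeline stage is independently reproducible
derive_seed <- function(seed, label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147480009
  as.integer((abs(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

# spatial dims of a channel-first tensor
.spatial_dim <- function(x) dim(x)[-1L]

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
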