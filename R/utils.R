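# Polynomial string hash over UTF-8 bytes, arithmetic kept in double precision
# modulo a Mersenne prime so it is exact and platform independent.
str_hash <- function(s, base = 31, mod = 2147483647) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 0
  for (b in bytes) h <- (h * base + b) %% mod
  h
}

#' Derive a reproducible sub-seed from a master seed and a purpose label
#'
#' Stage-level analyses draw their randomness from sub-seeds derived by stable
#' hashing of \code{(seed, purpose)}, so rerunning one stage in isolation
#' reproduces exactly what the full pipeline did.
#'
#' @param seed Integer master seed.
#' @param purpose Character label naming the consumer of the sub-seed.
#' @return An integer seed in \code{[0, 2^31)}.
#' @export
derive_seed <- function(seed, purpose) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(purpose))
  as.integer((abs(seed) * 1000003 + str_hash(purpose)) %% 2147483629)
}

# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Round half away from zero
#'
#' Percentage shares are printed with conventional half-up rounding (so
#' 0.125 -> 0.13), unlike \code{round()}'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Stable content hash (hex string) of an R object, used to stamp reports and
# pipeline artifacts with the configuration that produced them.
object_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 2147483647
    h2 <- (h2 * 37 + b + 1) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

chatmood_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "chatmood", mustWork = TRUE)
  path
}

#' English stopword list shipped with the package
#'
#' A fixed, versioned stopword list so n-gram results are reproducible across
#' installations (external NLP toolkits revise their lists between releases).
#'
#' @return Character vector of lowercase stopwords.
#' @export
chatmood_stopwords <- function() {
  readLines(chatmood_extdata("stopwords_en.txt"), encoding = "UTF-8")
}
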