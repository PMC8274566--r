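# internal helpers shared across modules

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so simulation calls do not perturb user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Stable 31-bit string hash (polynomial rolling hash). Used to derive
## per-scenario and per-replication seeds from a descriptor so that adding a
## scenario to a grid never perturbs the streams of the others.
hash_seed <- function(descriptor, master_seed = 0L, index = 0L) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(descriptor)) h <- (h * 31 + b) %% m
  as.integer((h + (as.numeric(master_seed) %% m) * 7919 +
                (as.numeric(index) %% m) * 104729) %% m)
}

gs_log <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## named-vector accessor with recycling of a scalar default across traits
trait_vec <- function(x, traits = c("GY", "AD", "PH")) {
  if (length(x) == 1L && is.null(names(x))) x <- rep(x, length(traits))
  if (is.null(names(x))) names(x) <- traits
  x[traits]
}
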