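#' @keywords internal
"_PACKAGE"

GRADES <- c("VL", "L", "M", "H", "VH")
FACTORS <- c("substrate", "temperature", "velocity", "depth")

# grade rank for ordering consequents (VL lowest)
.grade_rank <- function(g) match(g, GRADES)

.msg <- function(...) {
  if (isTRUE(getOption("spawnhab.verbose", FALSE))) message(...)
}

# evaluate a block with a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
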