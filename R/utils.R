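## run expr with a fixed seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a per-stage child seed from a pipeline seed
#'
#' Fans one global seed out to stage-local seeds by a fixed affine hash
#' modulo 2^31 - 1, so any stage can be re-run in isolation with the same
#' stream it saw inside the full pipeline.
#'
#' @param seed integer pipeline seed.
#' @param stage integer stage index (>= 1).
#' @return integer child seed in [1, 2^31 - 2].
#' @export
childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage) * 104729) %%
             2147483646 + 1)
}
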