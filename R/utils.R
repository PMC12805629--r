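# Evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
withLocalSeed <- function(seed, expr) {
    has_seed <- exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' @importFrom stats rbinom rpois rnbinom runif rgamma
#' @importFrom utils write.table
NULL
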