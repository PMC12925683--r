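# Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. All user-facing randomness in the package goes through this.
withLocalSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                integer = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
        stop(sprintf("'%s' must be a single non-missing number", name),
             call. = FALSE)
    if (integer && x != round(x))
        stop(sprintf("'%s' must be a whole number", name), call. = FALSE)
    if (x < lower || x > upper)
        stop(sprintf("'%s' must be in [%s, %s]", name,
                     format(lower), format(upper)), call. = FALSE)
    invisible(x)
}

## Extract the variants-by-samples dosage matrix from a GenotypeCohort or
## pass a plain matrix through unchanged.
.dosageMatrix <- function(x) {
    if (is(x, "GenotypeCohort"))
        return(dosage(x))
    if (is.matrix(x)) {
        storage.mode(x) <- "double"
        return(x)
    }
    stop("expected a GenotypeCohort or a variants-by-samples dosage matrix",
         call. = FALSE)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}
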