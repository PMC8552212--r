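## Internal helpers.

## Evaluate expr under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
        if (had) assign(".Random.seed", old, envir = env)
        else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env)
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

## Cheap content fingerprint of a numeric matrix (md5 of its serialization).
.matrixFingerprint <- function(X) {
    tf <- tempfile()
    on.exit(unlink(tf))
    con <- file(tf, "wb")
    serialize(X, con, version = 2)
    close(con)
    unname(tools::md5sum(tf))
}

## Squared Euclidean cross-distances between rows of A (n x d) and B (m x d).
.crossDist2 <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    d2[d2 < 0] <- 0
    d2
}
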