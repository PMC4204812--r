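# Shared fixtures, built in code. Small grids keep the suite fast while
# leaving every geometric property intact.

# a modest ellipsoid phantom at 2 mm spacing shared across replay tests
phantomFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- syntheticBrain(semiAxes = c(22, 18, 16), spacing = 2,
                                     shellThickness = 4)
        cache
    }
})

# random but reproducible parameter rows with motion of realistic size
randomParamRows <- function(n, seed, transSd = 0.5, rotSd = 0.01) {
    set.seed(seed)
    cbind(matrix(rnorm(3 * n, 0, transSd), n, 3),
          matrix(rnorm(3 * n, 0, rotSd), n, 3))
}

# brute-force Monte-Carlo sphere displacement oracle, independent of the
# Fibonacci-lattice implementation path
bruteSphereDisplacement <- function(row, d, nPoints, seed) {
    set.seed(seed)
    z <- runif(nPoints, -1, 1)
    phi <- runif(nPoints, 0, 2 * pi)
    r <- sqrt(1 - z^2)
    p <- d * cbind(r * cos(phi), r * sin(phi), z)
    m <- transformMatrix(paramsToTransform(row))
    moved <- sweep(p %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
    mean(sqrt(rowSums((moved - p)^2)))
}
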