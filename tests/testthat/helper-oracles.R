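# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the package's own primitives (distance transform, BFS labelling).

# small centered spherical-shell phantom on an isotropic cube
shell_fixture <- function(n = 24, outer = 9, inner = 6.5, spacing = c(1, 1, 1)) {
    g <- volume_grid(c(n, n, n), spacing)
    ctr <- (n - 1) / 2 * spacing
    list(grid = g, center = ctr,
         skull = make_skull(g, shell_geometry(ctr, outer, inner)))
}

# brute-force all-pairs min distance from each voxel to the mask (mm)
oracle_distance <- function(voxels, spacing) {
    sh <- dim(voxels)
    idx <- as.matrix(expand.grid(seq_len(sh[1]), seq_len(sh[2]),
                                 seq_len(sh[3])))
    pos <- sweep(idx - 1, 2, spacing, "*")
    src <- pos[voxels == 1L, , drop = FALSE]
    if (nrow(src) == 0L) return(array(Inf, dim = sh))
    d <- apply(pos, 1L, function(p)
        sqrt(min(colSums((t(src) - p)^2))))
    array(d, dim = sh)
}

# flood fill of the complement from the grid border (6-connected, array-shift
# dilation); returns logical array of enclosed complement voxels
oracle_enclosed <- function(skull_voxels) {
    comp <- skull_voxels == 0L
    sh <- dim(comp)
    reach <- array(FALSE, dim = sh)
    reach[c(1, sh[1]), , ] <- comp[c(1, sh[1]), , ]
    reach[, c(1, sh[2]), ] <- reach[, c(1, sh[2]), ] | comp[, c(1, sh[2]), ]
    reach[, , c(1, sh[3])] <- reach[, , c(1, sh[3])] | comp[, , c(1, sh[3])]
    shift6 <- function(a) {
        out <- array(FALSE, dim = dim(a))
        out[-1, , ] <- out[-1, , ] | a[-dim(a)[1], , ]
        out[-dim(a)[1], , ] <- out[-dim(a)[1], , ] | a[-1, , ]
        out[, -1, ] <- out[, -1, ] | a[, -dim(a)[2], ]
        out[, -dim(a)[2], ] <- out[, -dim(a)[2], ] | a[, -1, ]
        out[, , -1] <- out[, , -1] | a[, , -dim(a)[3]]
        out[, , -dim(a)[3]] <- out[, , -dim(a)[3]] | a[, , -1]
        out
    }
    repeat {
        grown <- (reach | shift6(reach)) & comp
        if (identical(grown, reach)) break
        reach <- grown
    }
    comp & !reach
}

# independent statement of the subtype rule as a decision table
oracle_rule <- function(b, d, i) {
    key <- paste(b > 0, d > 0, i > 0)
    base <- c("TRUE FALSE FALSE" = "POM",
              "TRUE TRUE FALSE"  = "SOM_I",
              "FALSE FALSE FALSE" = "not_osteomeningioma",
              "FALSE TRUE FALSE" = "not_osteomeningioma",
              "FALSE FALSE TRUE" = "not_osteomeningioma",
              "FALSE TRUE TRUE"  = "not_osteomeningioma",
              "TRUE FALSE TRUE"  = "skipped_layer")
    if (key %in% names(base)) return(unname(base[key]))
    if (b >= i) "SOM_IIA" else "SOM_IIB"
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher <- function(a, b, c, d) {
    m1 <- a + b; m2 <- c + d; k <- a + c
    lo <- max(0, k - m2); hi <- min(k, m1)
    probs <- dhyper(lo:hi, m1, m2, k)
    p_obs <- dhyper(a, m1, m2, k)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H by the rank formula with the tie-correction divisor
oracle_kw <- function(groups) {
    x <- unlist(groups)
    N <- length(x)
    r <- rank(x)
    ni <- vapply(groups, length, integer(1))
    gi <- rep(seq_along(groups), ni)
    rbar <- tapply(r, gi, mean)
    H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# seeded random binary mask
random_mask <- function(shape, p = 0.3, seed = 1, spacing = c(1, 1, 1)) {
    set.seed(seed)
    binary_mask(array(rbinom(prod(shape), 1, p), dim = shape),
                volume_grid(shape, spacing))
}
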