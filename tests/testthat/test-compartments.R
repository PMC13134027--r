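test_that("distance transform equals the brute-force all-pairs oracle", {
    for (case in list(list(sh = c(12, 12, 12), sp = c(1, 1, 1), seed = 1),
                      list(sh = c(10, 12, 8), sp = c(1, 1, 2), seed = 2),
                      list(sh = c(9, 7, 11), sp = c(0.5, 1, 2), seed = 3))) {
        m <- random_mask(case$sh, p = 0.1, seed = case$seed, spacing = case$sp)
        got <- mask_distance_mm(m)
        expect_equal(got, oracle_distance(m$voxels, case$sp), tolerance = 1e-10)
    }
    # empty mask: infinite everywhere
    empty <- binary_mask(array(0L, dim = c(4, 4, 4)))
    expect_true(all(is.infinite(mask_distance_mm(empty))))
})

test_that("cavity of a closed shell matches the flood-fill oracle", {
    fx <- shell_fixture(n = 42, outer = 20, inner = 16,
                        spacing = c(1, 1, 1))
    cav <- extract_intracranial_cavity(fx$skull, layer_spec())
    enclosed <- oracle_enclosed(fx$skull$voxels)
    expect_identical(cav$voxels == 1L, enclosed)
    expect_equal(sum(cav$voxels == 1L & fx$skull$voxels == 1L), 0L)
    # every cavity voxel center lies strictly inside the inner radius
    idx <- which(cav$voxels == 1L, arr.ind = TRUE)
    d <- sqrt(rowSums(sweep(idx - 1, 2, fx$center, "-")^2))
    expect_true(all(d < 16))
})

test_that("a solid skull has no cavity and the error advises sealing", {
    g <- volume_grid(c(16, 16, 16))
    solid <- make_skull(g, shell_geometry(c(7.5, 7.5, 7.5), 6, 0.4))
    solid$voxels[8, 8, 8] <- 1L  # fill the sub-voxel core
    expect_error(extract_intracranial_cavity(solid, layer_spec()),
                 "no enclosed cavity")
})

test_that("a perforated shell seals back to the closed-shell cavity", {
    fx <- shell_fixture(n = 32, outer = 12, inner = 9)
    cav_closed <- extract_intracranial_cavity(fx$skull, layer_spec())
    punct <- fx$skull
    hole <- which(punct$voxels == 1L, arr.ind = TRUE)
    hole <- hole[hole[, 2] == 16 & hole[, 3] == 16 & hole[, 1] > 16, , drop = FALSE]
    punct$voxels[hole[, 1], 16, 16] <- 0L  # 1-voxel-wide radial tunnel
    expect_error(extract_intracranial_cavity(
        punct, layer_spec(closing_radius_mm = 0)), "no enclosed cavity")
    cav_sealed <- extract_intracranial_cavity(
        punct, layer_spec(closing_radius_mm = 2))
    # sealing recovers the enclosed region up to the perforation voxel itself
    diff <- sum(cav_sealed$voxels != cav_closed$voxels)
    expect_lte(diff, 1L)
    expect_gte(mask_count(cav_sealed), mask_count(cav_closed))
})

test_that("the juxta-osseous layer is a metric band: half-space slab example", {
    # skull occupies x <= 2 (indices 1:2 at 1 mm), cavity x in 3:10
    sh <- c(12, 5, 5)
    sk <- array(0L, dim = sh); sk[1:2, , ] <- 1L
    cav <- array(0L, dim = sh); cav[3:10, , ] <- 1L
    skull <- binary_mask(sk); cavity <- binary_mask(cav)
    lay <- make_juxtaosseous_layer(skull, cavity, layer_spec(thickness_mm = 2))
    expect_true(all(lay$voxels[3:4, , ] == 1L))
    expect_true(all(lay$voxels[-(3:4), , ] == 0L))
    # thickness 0: empty (skull and cavity disjoint)
    lay0 <- make_juxtaosseous_layer(skull, cavity, layer_spec(thickness_mm = 0))
    expect_equal(mask_count(lay0), 0L)
})

test_that("anisotropic spacing changes how many voxel planes 2 mm captures", {
    sh <- c(12, 5, 12)
    g <- volume_grid(sh, c(1, 1, 2))
    skx <- array(0L, dim = sh); skx[1:2, , ] <- 1L
    cavx <- array(0L, dim = sh); cavx[3:10, , ] <- 1L
    layx <- make_juxtaosseous_layer(binary_mask(skx, g), binary_mask(cavx, g),
                                    layer_spec(2))
    expect_equal(sum(apply(layx$voxels, 1, sum) > 0), 2L)  # x=3,4 at 1 mm

    skz <- array(0L, dim = sh); skz[, , 1:2] <- 1L
    cavz <- array(0L, dim = sh); cavz[, , 3:10] <- 1L
    layz <- make_juxtaosseous_layer(binary_mask(skz, g), binary_mask(cavz, g),
                                    layer_spec(2))
    expect_equal(sum(apply(layz$voxels, 3, sum) > 0), 1L)  # z=3 only at 2 mm
})

test_that("layer equals the brute-force distance oracle and nests in thickness", {
    fx <- shell_fixture(n = 20, outer = 8, inner = 6)
    cav <- extract_intracranial_cavity(fx$skull, layer_spec())
    d <- oracle_distance(fx$skull$voxels, c(1, 1, 1))
    lay_prev <- NULL
    for (t in c(1, 2, 3, 5)) {
        lay <- make_juxtaosseous_layer(fx$skull, cav, layer_spec(t))
        expect_identical(lay$voxels == 1L, cav$voxels == 1L & d <= t)
        expect_true(all(lay$voxels <= cav$voxels))  # subset of cavity
        if (!is.null(lay_prev))
            expect_true(all(lay_prev$voxels <= lay$voxels))  # nesting
        lay_prev <- lay
    }
})

test_that("the compartment map partitions the grid with osseous priority", {
    fx <- shell_fixture()
    spec <- layer_spec(5)
    cav <- extract_intracranial_cavity(fx$skull, spec)
    lay <- make_juxtaosseous_layer(fx$skull, cav, spec)
    cm <- build_compartment_map(fx$skull, lay, cav, spec)
    expect_true(all(cm$labels %in% 0:3))
    expect_equal(sum(tabulate(cm$labels + 1L, 4L)), prod(fx$grid$shape))
    # label 1 equals the skull exactly; 2 u 3 equals the cavity exactly
    expect_identical(cm$labels == 1L, fx$skull$voxels == 1L)
    expect_identical(cm$labels >= 2L, cav$voxels == 1L)
    # set-operation oracle: skull; cavity & dist<=t; cavity \ layer
    d <- oracle_distance(fx$skull$voxels, c(1, 1, 1))
    oracle <- array(0L, dim = fx$grid$shape)
    oracle[cav$voxels == 1L & d <= 5] <- 2L
    oracle[cav$voxels == 1L & d > 5] <- 3L
    oracle[fx$skull$voxels == 1L] <- 1L
    expect_identical(cm$labels, oracle)
})

test_that("overlapping inputs resolve by priority osseous > layer > intradural", {
    sh <- c(4, 4, 4)
    one <- binary_mask(array(1L, dim = sh))
    cm <- build_compartment_map(one, one, one, layer_spec())
    expect_true(all(cm$labels == 1L))
    zero <- binary_mask(array(0L, dim = sh))
    cm2 <- build_compartment_map(zero, one, one, layer_spec())
    expect_true(all(cm2$labels == 2L))
    cm0 <- build_compartment_map(zero, zero, zero, layer_spec())
    expect_true(all(cm0$labels == 0L))
})

test_that("the shell compartment map is invariant under all 48 cube symmetries", {
    fx <- shell_fixture(n = 16, outer = 6, inner = 4)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(2))
    ref <- cm$labels
    flips <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                         f3 = c(FALSE, TRUE))
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    apply_sym <- function(a, perm, fl) {
        a <- aperm(a, perm)
        if (fl[1]) a <- a[rev(seq_len(dim(a)[1])), , ]
        if (fl[2]) a <- a[, rev(seq_len(dim(a)[2])), ]
        if (fl[3]) a <- a[, , rev(seq_len(dim(a)[3]))]
        a
    }
    for (p in perms) for (r in seq_len(nrow(flips))) {
        sk2 <- binary_mask(apply_sym(fx$skull$voxels, p, unlist(flips[r, ])),
                           fx$grid)
        cm2 <- compartment_map_from_skull(sk2, layer_spec(2))
        expect_identical(cm2$labels, apply_sym(ref, p, unlist(flips[r, ])))
    }
})

test_that("compartment maps round-trip through NIfTI with a JSON sidecar", {
    fx <- shell_fixture(n = 16, outer = 6, inner = 4)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(3))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    write_compartment_map(cm, f)
    back <- RNifti::readNifti(f)
    expect_equal(array(as.integer(back), dim = dim(back)), cm$labels)
    side <- jsonlite::read_json(sub("\\.nii\\.gz$", ".json", f))
    expect_equal(side$layer$thickness_mm, 3)
    expect_equal(side$labels$juxta_osseous, 2)
})
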