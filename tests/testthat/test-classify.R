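test_that("the subtype rule matches the decision-table oracle exhaustively", {
    for (b in 0:6) for (d in 0:6) for (i in 0:6) {
        call <- classify_osteomeningioma(compartment_counts(b, d, i))
        want <- oracle_rule(b, d, i)
        if (want %in% subtype_levels()) {
            expect_true(call$valid)
            expect_identical(call$subtype, want)
        } else {
            expect_false(call$valid)
            expect_identical(call$anomaly, want)
        }
        # purity: same counts give the same call
        expect_identical(
            classify_osteomeningioma(compartment_counts(b, d, i))$subtype,
            call$subtype)
    }
})

test_that("named rule examples classify as stated and n_other never matters", {
    expect_identical(
        classify_osteomeningioma(compartment_counts(10, 0, 0))$subtype, "POM")
    expect_identical(
        classify_osteomeningioma(compartment_counts(100, 50, 100))$subtype,
        "SOM_IIA")  # equality goes to SOM-IIA
    expect_identical(
        classify_osteomeningioma(compartment_counts(5, 10, 20))$subtype,
        "SOM_IIB")
    inv <- classify_osteomeningioma(compartment_counts(0, 7, 3))
    expect_false(inv$valid)
    expect_identical(inv$anomaly, "not_osteomeningioma")
    with_other <- classify_osteomeningioma(compartment_counts(5, 10, 20, 999))
    expect_identical(with_other$subtype, "SOM_IIB")
})

test_that("voxel counting is exact against generator ground truth", {
    fx <- shell_fixture(n = 28, outer = 11, inner = 8.5)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(5))
    les <- make_lesion_by_counts(cm, 120, 40, 60, 0, seed = 42)
    got <- count_compartment_voxels(les$mask, cm)
    expect_equal(got$n_bone, 120L)
    expect_equal(got$n_dura, 40L)
    expect_equal(got$n_intra, 60L)
    expect_equal(got$n_other, 0L)
    expect_equal(got$total, 220L)
    expect_equal(sum(got$pct), 1, tolerance = 1e-9)
    # empty tumor
    empty <- binary_mask(array(0L, dim = fx$grid$shape), fx$grid)
    z <- count_compartment_voxels(empty, cm)
    expect_equal(z$total, 0L)
    expect_true(all(is.na(z$pct)))
    # tumor entirely outside all compartments
    blob <- array(0L, dim = fx$grid$shape); blob[1, 1, 1] <- 1L
    o <- count_compartment_voxels(binary_mask(blob, fx$grid), cm)
    expect_equal(o$n_other, o$total)
})

test_that("component volumes follow the count x voxel-volume conversion", {
    v <- component_volumes(compartment_counts(22400, 0, 0,
                                              voxel_volume_mm3 = 1))
    expect_equal(v$osseous_cm3, 22.4)
    expect_equal(v$intracranial_soft_tissue_cm3, 0)
    v2 <- component_volumes(compartment_counts(0, 0, 0, voxel_volume_mm3 = 1))
    expect_equal(unlist(v2), c(osseous_cm3 = 0,
                               intracranial_soft_tissue_cm3 = 0,
                               other_cm3 = 0, total_cm3 = 0))
    v3 <- component_volumes(compartment_counts(8000, 0, 0,
                                               voxel_volume_mm3 = 0.125))
    expect_equal(v3$osseous_cm3, 1)
    v4 <- component_volumes(compartment_counts(10, 20, 30,
                                               voxel_volume_mm3 = 2))
    expect_equal(v4$intracranial_soft_tissue_cm3, 50 * 2 / 1000)
    expect_equal(v4$total_cm3, 60 * 2 / 1000)
})

test_that("classify_case matches the oracle pipeline on a transmural sphere", {
    fx <- shell_fixture(n = 32, outer = 12, inner = 9)
    spec <- layer_spec(5)
    cm <- compartment_map_from_skull(fx$skull, spec)
    # sphere centered on the inner table (9 mm from shell center)
    ctr <- fx$center + c(9, 0, 0)
    tum <- make_transmural_sphere(fx$grid, ctr, 8)
    cs <- case_inputs("sph", tum, fx$skull)
    call <- classify_case(cs, spec)
    # oracle counts: direct cross-tabulation of the sphere on the oracle map
    d <- oracle_distance(fx$skull$voxels, c(1, 1, 1))
    cav <- oracle_enclosed(fx$skull$voxels)
    lab <- array(0L, dim = fx$grid$shape)
    lab[cav & d <= 5] <- 2L; lab[cav & d > 5] <- 3L
    lab[fx$skull$voxels == 1L] <- 1L
    codes <- lab[tum$voxels == 1L]
    want <- classify_osteomeningioma(compartment_counts(
        sum(codes == 1L), sum(codes == 2L), sum(codes == 3L),
        sum(codes == 0L)))
    expect_identical(call$subtype, want$subtype)
    expect_equal(call$counts$n_bone, sum(codes == 1L))
    expect_equal(call$counts$n_intra, sum(codes == 3L))
})

test_that("bone-only and intradural-dominant phantom lesions call as built", {
    fx <- shell_fixture(n = 32, outer = 12, inner = 9)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(5))
    bone <- make_lesion_by_counts(cm, 80, 0, 0, seed = 1)
    cs_b <- case_inputs("b", bone$mask, fx$skull)
    expect_identical(classify_case(cs_b, layer_spec(5))$subtype, "POM")
    deep <- make_lesion_by_counts(cm, 20, 40, 120, seed = 2)
    cs_d <- case_inputs("d", deep$mask, fx$skull)
    expect_identical(classify_case(cs_d, layer_spec(5))$subtype, "SOM_IIB")
})

test_that("thickness monotonicity: counts and subtype order move one way", {
    fx <- shell_fixture(n = 30, outer = 11, inner = 8.5)
    cm5 <- compartment_map_from_skull(fx$skull, layer_spec(5))
    set.seed(99)
    lev <- subtype_levels()
    for (rep in 1:6) {
        les <- make_lesion_by_counts(cm5, sample(5:80, 1), sample(5:60, 1),
                                     sample(0:40, 1), seed = 200 + rep)
        cs <- case_inputs(paste0("m", rep), les$mask, fx$skull)
        prev <- NULL; prev_counts <- NULL
        for (t in c(5, 3, 2)) {  # decreasing thickness
            call <- classify_case(cs, layer_spec(t))
            expect_true(call$valid)
            if (!is.null(prev_counts)) {
                expect_gte(call$counts$n_intra, prev_counts$n_intra)
                expect_lte(call$counts$n_dura, prev_counts$n_dura)
                expect_equal(call$counts$n_bone, prev_counts$n_bone)
            }
            if (!is.null(prev))
                expect_gte(match(call$subtype, lev), match(prev, lev))
            prev <- call$subtype; prev_counts <- call$counts
        }
    }
})

test_that("POM and SOM-IIB calls are invariant to thickness", {
    fx <- shell_fixture(n = 28, outer = 10, inner = 7.5)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(5))
    pom <- make_lesion_by_counts(cm, 50, 0, 0, seed = 5)
    iib <- make_lesion_by_counts(cm, 5, 10, 60, seed = 6)
    for (t in c(2, 3, 5)) {
        expect_identical(classify_case(case_inputs("p", pom$mask, fx$skull),
                                       layer_spec(t))$subtype, "POM")
        expect_identical(classify_case(case_inputs("q", iib$mask, fx$skull),
                                       layer_spec(t))$subtype, "SOM_IIB")
    }
})

test_that("a constructed SOM-I lesion reclassifies when the layer thins", {
    # slab skull: bone plate x in 2:4, cavity x in 5:14
    g <- volume_grid(c(16, 16, 16))
    geo <- slab_geometry(1, c(2, 4), c(5, 14))
    skull <- make_skull(g, geo)
    # tumor: bone voxels at x=4 plus a dural tongue x=5..8, center cross-section
    tum <- array(0L, dim = c(16, 16, 16))
    tum[3:4, 8:9, 8:9] <- 1L
    tum[5:8, 8:9, 8:9] <- 1L
    cs <- case_inputs("slab", binary_mask(tum, g), skull)
    call5 <- classify_case(cs, layer_spec(5))
    call2 <- classify_case(cs, layer_spec(2))
    expect_identical(call5$subtype, "SOM_I")
    expect_identical(call2$subtype, "SOM_IIA")
})

test_that("thickness_sensitivity summarizes stability and transitions", {
    fx <- shell_fixture(n = 28, outer = 10, inner = 7.5)
    cm <- compartment_map_from_skull(fx$skull, layer_spec(5))
    mk <- function(b, d, i, seed) {
        les <- make_lesion_by_counts(cm, b, d, i, seed = seed)
        case_inputs(paste0("c", seed), les$mask, fx$skull)
    }
    bone_only <- lapply(1:3, function(s) mk(40, 0, 0, s))
    rec <- thickness_sensitivity(bone_only, c(2, 3, 5))
    expect_equal(rec$stable_fraction, 1)
    expect_true(all(rec$table$t5mm == "POM"))
    # transition matrix row sums equal source-thickness subtype counts
    mixed <- c(bone_only, list(mk(10, 30, 40, 7), mk(60, 30, 10, 8)))
    rec2 <- thickness_sensitivity(mixed, c(2, 5))
    tr <- rec2$transitions[[1]]
    expect_equal(sum(tr), length(mixed))
    expect_equal(as.vector(rowSums(tr)[rec2$table$t2mm[1]]) > 0, TRUE)
    expect_equal(nrow(rec2$table), length(mixed))
})
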