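# Stimulus generators: geometry, labels, determinism, splits, manifests.

test_that("fixture glyphs are deterministic, bounded and class-distinct", {
  src <- glyph_cache(120, seed = 1)
  src_again <- gen_fixture_glyphs(120, seed = 1)
  expect_identical(src$images, src_again$images)
  expect_true(all(vapply(src$images, function(i)
    all(i >= 0 & i <= 1) && all(dim(i) == c(28, 28)), logical(1))))
  expect_equal(sort(unique(src$labels)), 0:9)
  means <- lapply(0:9, function(cl)
    Reduce(`+`, src$images[src$labels == cl]) / sum(src$labels == cl))
  for (a in 1:9) for (b in (a + 1):10)
    expect_gt(mean(abs(means[[a]] - means[[b]])), 0)
  # train/test sources are disjoint random streams
  te <- gen_fixture_glyphs(20, seed = 1, split = "test")
  expect_false(identical(src$images[[1]], te$images[[1]]))
})

test_that("overlapping-digit samples obey canvas, label and shift rules", {
  src <- glyph_cache(120, seed = 1)
  ds <- gen_multimnist(src, 40, seed = 5)
  expect_s3_class(ds, "ocra_dataset")
  for (i in seq_len(40)) {
    expect_equal(dim(ds$images[[i]]), c(36, 36))
    expect_true(all(ds$images[[i]] >= 0 & ds$images[[i]] <= 1))
    expect_length(ds$labels[[i]], 2L)
    expect_false(ds$meta[[i]]$labels[1] == ds$meta[[i]]$labels[2])
    expect_true(all(abs(ds$meta[[i]]$offsets) <= 4))
  }
  # composite is the pixelwise max of the placed digits
  m <- ds$meta[[1]]
  rebuilt <- matrix(0, 36, 36)
  for (d in 1:2) {
    tl <- 5 + m$offsets[d, ]
    rebuilt[tl[1]:(tl[1] + 27), tl[2]:(tl[2] + 27)] <-
      pmax(rebuilt[tl[1]:(tl[1] + 27), tl[2]:(tl[2] + 27)],
           src$images[[m$src[d]]])
  }
  expect_equal(ds$images[[1]], rebuilt)
  # regeneration from (seed, index) is exact
  ds2 <- gen_multimnist(src, 40, seed = 5)
  expect_identical(ds$images, ds2$images)
  expect_error(gen_multimnist(list(), 5), "fixture")
})

test_that("frame-box overlap averages ~80% under the +/-4 pixel shifts", {
  src <- glyph_cache(120, seed = 1)
  ds <- gen_multimnist(src, 3000, seed = 6, keep_images = FALSE)
  ov <- overlap_statistic(ds, box = "frame", metric = "min")
  # closed-form expectation: E[(28-|dx|)(28-|dy|)]/784 with dx, dy the
  # difference of two independent U{-4..4} draws
  pdiff <- outer(-4:4, -4:4, "-")
  e1 <- mean(28 - abs(pdiff)) / 28
  expect_equal(e1 * e1, 0.7997, tolerance = 1e-3)
  expect_equal(ov, e1 * e1, tolerance = 0.01)
  # ink boxes give a strictly smaller IoU overlap
  expect_lt(overlap_statistic(ds, "ink", "iou"), ov)
})

test_that("cluttered samples place two digits and six 8x8 clutter crops", {
  src <- glyph_cache(120, seed = 1)
  ds <- gen_cluttered(src, 15, seed = 7)
  for (i in seq_len(15)) {
    expect_equal(dim(ds$images[[i]]), c(100, 100))
    expect_length(ds$labels[[i]], 2L)
    expect_equal(length(ds$meta[[i]]$clutter_src), 6L)
    expect_equal(dim(ds$meta[[i]]$clutter_pos), c(6L, 4L))
    # clutter never cropped from the digits on the same canvas
    expect_false(any(ds$meta[[i]]$clutter_src %in% ds$meta[[i]]$src))
  }
  # digits may share a class
  labs <- vapply(ds$meta, function(m) m$labels[1] == m$labels[2], logical(1))
  expect_type(labs, "logical")
  # with clutter suppressed, ink equals the two placed digits exactly
  ds0 <- gen_cluttered(src, 3, seed = 8, n_clutter = 0L)
  m <- ds0$meta[[1]]
  rebuilt <- matrix(0, 100, 100)
  for (d in 1:2)
    rebuilt <- ocra:::place(rebuilt, src$images[[m$src[d]]],
                            m$tops[d], m$lefts[d])
  expect_equal(ds0$images[[1]], rebuilt)
})

test_that("same-different stimuli satisfy their construction invariants", {
  sv <- gen_svrt1(60, seed = 9)
  expect_true(all(vapply(sv$images, function(i)
    all(dim(i) == c(64, 64)) && all(i %in% c(0, 1)), logical(1))))
  fams <- vapply(sv$meta, function(m) m$family, character(1))
  expect_true(all(fams %in% svrt_families("train")))
  # a "same" sample's two components are pixel-identical up to translation
  for (i in which(vapply(sv$labels, identical, logical(1), "same"))) {
    b <- sv$meta[[i]]$boxes
    p1 <- sv$images[[i]][b[1, 1]:b[1, 2], b[1, 3]:b[1, 4]]
    p2 <- sv$images[[i]][b[2, 1]:b[2, 2], b[2, 3]:b[2, 4]]
    expect_identical(p1, p2)
  }
  # "different" samples differ somewhere
  for (i in which(vapply(sv$labels, identical, logical(1), "different"))) {
    b <- sv$meta[[i]]$boxes
    p1 <- sv$images[[i]][b[1, 1]:b[1, 2], b[1, 3]:b[1, 4]]
    p2 <- sv$images[[i]][b[2, 1]:b[2, 2], b[2, 3]:b[2, 4]]
    expect_false(identical(dim(p1), dim(p2)) && all(p1 == p2))
  }
  # determinism
  sv2 <- gen_svrt1(60, seed = 9)
  expect_identical(sv$images, sv2$images)
  # class balance (Bernoulli 0.5 labels)
  svb <- gen_svrt1(600, seed = 10)
  p <- mean(unlist(svb$labels) == "same")
  expect_lt(abs(p - 0.5), 0.06)
})

test_that("OOD families are disjoint from the training families by name", {
  expect_length(svrt_families("train"), 9L)
  expect_length(svrt_families("ood"), 4L)
  expect_length(intersect(svrt_families("train"), svrt_families("ood")), 0L)
  sv <- gen_svrt1(12, seed = 11, ood = TRUE)
  fams <- vapply(sv$meta, function(m) m$family, character(1))
  expect_true(all(fams %in% svrt_families("ood")))
})

test_that("PNG + manifest round trips preserve images and labels", {
  src <- glyph_cache(120, seed = 1)
  dir <- withr::local_tempdir()
  ds <- gen_multimnist(src, 6, seed = 12)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_equal(length(back$labels), 6L)
  expect_equal(back$task, "multimnist")
  for (i in 1:6) {
    expect_equal(sort(back$labels[[i]]), sort(ds$labels[[i]]))
    expect_lt(max(abs(back$images[[i]] - ds$images[[i]])), 1 / 254)
  }
  # reasoning manifests carry the same/different column and family
  dir2 <- withr::local_tempdir()
  sv <- gen_svrt1(4, seed = 13)
  write_dataset(sv, dir2)
  back2 <- read_dataset(dir2)
  expect_identical(unlist(back2$labels), unlist(sv$labels))
  man <- utils::read.csv(file.path(dir2, "manifest.csv"))
  expect_true(all(c("filename", "split", "task", "label1", "label2",
                    "same_different", "family", "seed", "index")
                  %in% names(man)))
})
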