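test_that("default class prior reproduces the reported score distribution", {
  p <- default_class_prior()
  expect_length(p, 6L)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(unname(p[1]), 0.7526, tolerance = 2e-4)   # normal joints
  expect_equal(unname(p[6]), 0.0664, tolerance = 2e-4)   # score >= 5
  expect_equal(unname(p * sum(c(0.7526, 0.069, 0.0456, 0.0352, 0.0313, 0.0664))),
               c(0.7526, 0.0690, 0.0456, 0.0352, 0.0313, 0.0664))
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(class_prior = rep(0.2, 6)), "sum to 1")
  expect_error(generator_config(joint_size_range = c(0, 10)), "positive")
  expect_error(generator_config(image_size = 100, joint_size_range = c(8, 30)),
               "image_size / 4")
})

test_that("generated images are deterministic and structurally valid", {
  cfg <- generator_config(image_size = 96L, n_images = 3L,
                          joint_size_range = c(4, 10), seed = 5L)
  a <- generate_image(cfg, 2L)
  b <- generate_image(cfg, 2L)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$annotations, b$annotations)
  # independent of generation order / other indices
  other <- generate_image(cfg, 1L)
  expect_false(identical(other$image$pixels, a$image$pixels))
  c2 <- generate_image(cfg, 2L)
  expect_identical(c2$annotations, a$annotations)

  ann <- a$annotations
  expect_equal(nrow(ann), 32L)
  expect_setequal(ann$joint_id, 1:32)
  expect_true(all(ann$erosion_score %in% 0:5))
  expect_true(all(ann$x_min >= 0 & ann$y_min >= 0 &
                    ann$x_max <= 96 & ann$y_max <= 96))
  expect_true(all(pmin(ann$x_max - ann$x_min, ann$y_max - ann$y_min) >= 4))
  expect_true(all(a$image$pixels >= 0 & a$image$pixels <= 4096))
})

test_that("carpal joints form a tight cluster with small inter-box gaps", {
  cfg <- generator_config(image_size = 200L, n_images = 1L,
                          joint_size_range = c(8, 16), seed = 9L)
  it <- generate_image(cfg, 1L)
  ann <- it$annotations
  # carpal joints are the last 5 per hand under the generator's id layout
  for (ids in list(12:16, 28:32)) {
    cl <- ann[ann$joint_id %in% ids, ]
    size <- mean(cl$x_max - cl$x_min)
    cx <- (cl$x_min + cl$x_max) / 2
    cy <- (cl$y_min + cl$y_max) / 2
    d <- as.matrix(dist(cbind(cx, cy)))
    diag(d) <- Inf
    nearest <- apply(d, 1, min)
    # center spacing <= 1.25 * box size <=> inter-box gap <= 25% of box size
    expect_true(all(nearest <= 1.25 * size + 1e-9))
  }
})

test_that("empirical score frequencies follow the class prior", {
  cfg <- generator_config(image_size = 96L, n_images = 40L,
                          joint_size_range = c(4, 10), seed = 31L)
  scores <- unlist(lapply(seq_len(cfg$n_images), function(i) {
    generate_image(cfg, i)$annotations$erosion_score
  }))
  freq0 <- mean(scores == 0)
  expect_gt(freq0, 0.7526 - 0.05)   # binomial tolerance at n = 1280
  expect_lt(freq0, 0.7526 + 0.05)
})

test_that("erosion classes are separable by mean in-box intensity", {
  cfg <- generator_config(image_size = 128L, n_images = 25L,
                          joint_size_range = c(6, 12), seed = 77L)
  feats <- list(); labs <- integer(0)
  for (i in seq_len(cfg$n_images)) {
    it <- generate_image(cfg, i)
    px <- it$image$pixels
    for (r in seq_len(32)) {
      a <- it$annotations[r, ]
      sub <- px[max(1, floor(a$y_min + 1)):min(128, ceiling(a$y_max)),
                max(1, floor(a$x_min + 1)):min(128, ceiling(a$x_max))]
      feats[[length(feats) + 1L]] <- mean(sub)
      labs <- c(labs, a$erosion_score)
    }
  }
  f <- unlist(feats)
  # nearest-class-mean classifier on the scalar feature beats chance
  mu <- tapply(f, labs, mean)
  pred <- as.integer(names(mu))[apply(abs(outer(f, mu, "-")), 1, which.min)]
  acc <- mean(pred == labs)
  chance <- max(table(labs)) / length(labs)
  expect_gt(acc, 0.25)
  # and the feature decreases monotonically with the score
  expect_true(all(diff(mu[as.character(0:5)]) < 0))
})

test_that("splits are disjoint by patient and sized by the fractions", {
  cfg <- generator_config(image_size = 96L, n_images = 10L,
                          joint_size_range = c(4, 10), seed = 2L)
  sp <- generate_split(cfg)
  expect_named(sp, c("train", "validation", "test"))
  expect_equal(vapply(sp, function(s) length(s$items), integer(1)),
               c(train = 7L, validation = 1L, test = 2L))
  ids <- unlist(lapply(sp, function(s) s$patient_ids))
  expect_equal(anyDuplicated(ids), 0L)
  # reproducible
  sp2 <- generate_split(cfg)
  expect_identical(lapply(sp$train$items, function(i) i$patient_id),
                   lapply(sp2$train$items, function(i) i$patient_id))
  expect_error(generate_split(cfg, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("a synthetic dataset can be written and read back", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(image_size = 96L, n_images = 2L,
                          joint_size_range = c(4, 10), seed = 3L)
  ds <- generate_dataset(cfg)
  write_synthetic_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_annotations(file.path(dir, "annotations.csv"), load_images = TRUE)
  expect_length(back, 2L)
  expect_equal(back[[1]]$annotations, ds$items[[1]]$annotations)
  expect_lt(max(abs(back[[1]]$image$pixels - ds$items[[1]]$image$pixels)), 0.1)
})
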