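# Diffusion algebra, Eq.-style lesion proportions, DDIM determinism.

test_that("lesion proportions are counts normalised by the dataset maximum", {
  labs <- lapply(c(10, 20, 40), wmh_label_2d)
  expect_equal(lesion_proportion(labs, "WMH"), c(0.25, 0.5, 1.0))
  # all-zero lesion type degenerates to zeros, not NaN
  expect_equal(lesion_proportion(labs, "oedema"), c(0, 0, 0))
  expect_error(lesion_proportion(labs, "glioma"), "unknown")
  expect_error(lesion_proportion(list(), "WMH"), "empty")
  # random fixture vs independent recount
  set.seed(12)
  ns <- sample(0:30, 5)
  labs2 <- lapply(ns, wmh_label_2d)
  manual <- vapply(labs2, function(l) sum(l$probs[6, , ] > 0.5), numeric(1))
  expect_equal(lesion_proportion(labs2, "WMH"), manual / max(manual))
})

test_that("relative slice number is index over max dimension", {
  expect_equal(relative_slice_number(128, 256), 0.5)
  expect_equal(relative_slice_number(0, 256), 0)
  expect_equal(relative_slice_number(255, 256), 0.99609375)
  expect_error(relative_slice_number(256, 256), "out of")
  expect_error(relative_slice_number(-1, 256), "out of")
})

test_that("noise schedule satisfies the cumulative-product identity", {
  sch <- make_schedule(1000)
  expect_true(all(sch$beta > 0 & sch$beta < 1))
  expect_true(all(diff(sch$alpha_bar) < 0))
  direct <- vapply(seq_len(1000), function(t) prod(sch$alpha[1:t]),
                   numeric(1))
  expect_lt(max(abs(sch$alpha_bar - direct)), 1e-12)
  expect_lt(max(abs(sch$alpha_bar[-1] -
                      sch$alpha_bar[-1000] * sch$alpha[-1])), 1e-12)
  s1 <- make_schedule(1)
  expect_equal(s1$alpha_bar, 1 - s1$beta)
  expect_error(make_schedule(0), ">= 1")
})

test_that("forward diffusion hits its closed-form limits and moments", {
  x0 <- array(rnorm(12), c(2, 2, 3, 1))
  eps <- array(rnorm(12), c(2, 2, 3, 1))
  sch1 <- structure(list(T = 2L, beta = c(0, 1), alpha = c(1, 0),
                         alpha_bar = c(1, 0)), class = "noise_schedule")
  expect_equal(forward_diffuse(x0, 1, eps, sch1), x0)       # alpha_bar = 1
  expect_equal(forward_diffuse(x0, 2, eps, sch1), eps)      # alpha_bar = 0
  expect_error(forward_diffuse(x0, 3, eps, sch1), "out of")
  sch <- make_schedule(1000)
  t <- 400
  set.seed(13)
  draws <- replicate(1e4, forward_diffuse(0, t, rnorm(1), sch))
  expect_equal(stats::var(draws), 1 - sch$alpha_bar[t],
               tolerance = 0.05 * (1 - sch$alpha_bar[t]))
})

test_that("epsilon-prediction loss matches elementwise oracles", {
  sch <- make_schedule(100)
  x0 <- array(rnorm(24), c(2, 2, 3, 2))
  eps <- array(rnorm(24), c(2, 2, 3, 2))
  t <- c(10, 60)
  oracle_denoiser <- function(x_t, t, cond) {
    ab <- rep(sch$alpha_bar[t], each = 12)
    (x_t - sqrt(ab) * x0) / sqrt(1 - ab)
  }
  expect_lt(dm_loss(oracle_denoiser, x0, NULL, t, eps, sch), 1e-24)
  zero_denoiser <- function(x_t, t, cond) x_t * 0
  expect_equal(dm_loss(zero_denoiser, x0, NULL, t, eps, sch), mean(eps^2))
  # large-grid expectation: loss of the zero denoiser concentrates near 1
  set.seed(14)
  big_eps <- array(rnorm(4096), c(32, 32, 4, 1))
  expect_equal(dm_loss(zero_denoiser, big_eps * 0, NULL, 50, big_eps, sch),
               1, tolerance = 0.1)
})

test_that("DDIM is deterministic and matches an analytic linear recursion", {
  sch <- make_schedule(50)
  a <- 0.3
  lin_denoiser <- function(x_t, t, cond) a * x_t
  cond <- matrix(0.5, 2, 5)
  z1 <- ddim_sample(lin_denoiser, cond, n_steps = 50, rng_seed = 21,
                    schedule = sch, latent_shape = c(2, 2, 3),
                    clip_x0 = Inf)
  z2 <- ddim_sample(lin_denoiser, cond, n_steps = 50, rng_seed = 21,
                    schedule = sch, latent_shape = c(2, 2, 3),
                    clip_x0 = Inf)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(2L, 2L, 3L, 2L))
  # independent recursion on the scalar multiplier
  ts <- 50:1
  k <- 1
  for (i in seq_along(ts)) {
    abt <- sch$alpha_bar[ts[i]]
    abp <- if (i < length(ts)) sch$alpha_bar[ts[i + 1]] else 1
    c0 <- (1 - sqrt(1 - abt) * a) / sqrt(abt)
    k <- k * (sqrt(abp) * c0 + sqrt(1 - abp) * a)
  }
  x_T <- with_seed(21, array(rnorm(24), c(2, 2, 3, 2)))
  expect_equal(z1, k * x_T, tolerance = 1e-10)
  expect_error(ddim_sample(lin_denoiser, cond, n_steps = 51, rng_seed = 1,
                           schedule = sch, latent_shape = c(2, 2, 3)),
               "exceeds")
})

test_that("batched cross-attention gradients match finite differences", {
  set.seed(51)
  N <- 2; d <- 4; nc <- 3; hh <- 2; ww <- 2
  HW <- hh * ww
  m <- function(f) getFromNamespace(f, "mrisynth")
  run <- function(qv, t1v, value_only = TRUE) {
    q <- mrisynth:::nn_node(qv, req = TRUE)
    tok0 <- mrisynth:::nn_const(matrix(0.3, nc, d))
    tok1 <- mrisynth:::nn_node(t1v, req = TRUE)
    kw <- mrisynth:::nn_const(diag(d)); vw <- mrisynth:::nn_const(diag(d) * 0.5)
    zb <- mrisynth:::nn_const(numeric(d))
    cond <- matrix(seq(0.1, 0.6, length.out = N * nc), N)
    K0 <- mrisynth:::nn_dense(tok0, kw, zb)
    K1 <- mrisynth:::nn_matmul(tok1, kw)
    V0 <- mrisynth:::nn_dense(tok0, vw, zb)
    V1 <- mrisynth:::nn_matmul(tok1, vw)
    Qall <- mrisynth:::nn_reshape(mrisynth:::nn_aperm(q, c(1, 2, 4, 3)),
                                  c(HW * N, d))
    cs <- mrisynth:::nn_const(cond[rep(seq_len(N), each = HW), , drop = FALSE])
    S <- mrisynth:::nn_mulc(
      mrisynth:::nn_add(mrisynth:::nn_matmul(Qall, mrisynth:::nn_transpose(K0)),
                        mrisynth:::nn_mul(mrisynth:::nn_matmul(
                          Qall, mrisynth:::nn_transpose(K1)), cs)),
      1 / sqrt(d))
    A <- mrisynth:::nn_softmax_rows(S)
    O <- mrisynth:::nn_add(mrisynth:::nn_matmul(A, V0),
                           mrisynth:::nn_matmul(mrisynth:::nn_mul(A, cs), V1))
    loss <- mrisynth:::nn_sum(mrisynth:::nn_pow(O, 2))
    if (value_only) loss$value else list(loss = loss, q = q, tok1 = tok1)
  }
  qv <- array(rnorm(HW * d * N), c(hh, ww, d, N))
  t1v <- matrix(rnorm(nc * d) * 0.5, nc)
  g <- run(qv, t1v, value_only = FALSE)
  mrisynth:::nn_backward(g$loss)
  gq <- numeric_grad(function(v) run(array(v, dim(qv)), t1v), qv)
  gt <- numeric_grad(function(v) run(qv, matrix(v, nc)), t1v)
  expect_lt(max(abs(gq - g$q$grad)), 1e-6)
  expect_lt(max(abs(gt - g$tok1$grad)), 1e-6)
})

test_that("the sampling-path denoiser matches the training-graph forward", {
  set.seed(33)
  pp <- with_seed(3, mrisynth:::.denoiser_new_params(3, 24, 5))
  x <- array(rnorm(8 * 8 * 3 * 4), c(8, 8, 3, 4))
  t <- c(10, 500, 900, 44)
  cond <- matrix(runif(20), 4, 5)
  a <- mrisynth:::.denoiser_fwd(pp, x, t, cond, 1000)$value
  b <- mrisynth:::.denoiser_eval(pp, x, t, cond, 1000)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("two-stage contract: diffusion training demands a frozen VAE", {
  fake_vae <- structure(list(frozen = FALSE), class = "label_vae")
  expect_error(train_label_diffusion(fake_vae, list(wmh_label_2d(3))),
               "frozen")
  expect_error(train_label_diffusion(structure(list(frozen = TRUE),
                                               class = "not_a_vae"),
                                     list()), "frozen|label_vae")
})

test_that("2D conditioning has exactly one extra dimension over lesion-only", {
  labs <- lapply(c(5, 10), function(n) {
    l <- wmh_label_2d(n, 8, 8); l$slice_index <- n; l
  })
  c2d <- mrisynth:::.build_conditioning(labs, slice_cond = TRUE,
                                        slice_max_dim = 16)
  c3d <- mrisynth:::.build_conditioning(labs, slice_cond = FALSE,
                                        slice_max_dim = NULL)
  expect_equal(ncol(c2d), ncol(c3d) + 1)
  expect_equal(colnames(c2d), c(mrisynth:::COND_LESIONS, "slice"))
  expect_equal(c2d[, "slice"], c(5, 10) / 16)
})

test_that("sample_labels validates conditioning and handles empty requests", {
  stack <- trained_label_stack()
  expect_identical(sample_labels(stack$vae, stack$ldm,
                                 matrix(numeric(0), 0, 5)), list())
  expect_error(sample_labels(stack$vae, stack$ldm,
                             matrix(c(2, 0, 0, 0, 0.5), 1)), "\\[0, 1\\]")
  labs <- sample_labels(stack$vae, stack$ldm,
                        matrix(c(0.5, 0, 0, 0, 0.5), 1), n_steps = 20,
                        rng_seed = 4)
  expect_true(validate_label(labs[[1]]))
})
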