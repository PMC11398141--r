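# Assembled network: shape contracts, ablation grid, structural counts,
# mask binarisation, checkpointing.

ablation_grid <- list(
  c(FALSE, FALSE, FALSE), c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
  c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE)
)

test_that("forward shapes and probability ranges hold for desk-scale inputs", {
  net <- rheu_net(network_config(base_width = 4, seed = 61))
  x <- rand_fmap(96, 96, 1, 3, seed = 62)
  suppressWarnings(out <- rheu_forward(net, x))
  expect_identical(dim(out$probabilities), c(96L, 96L, 1L, 2L))
  expect_identical(dim(out$logits), dim(out$probabilities))
  expect_true(all(out$probabilities > 0 & out$probabilities < 1))
  expect_equal(out$probabilities, 1 / (1 + exp(-out$logits)), tolerance = 1e-12)
})

test_that("indivisible input sizes raise an error naming the required multiple", {
  net <- rheu_net(network_config(base_width = 2, seed = 63))
  expect_error(nn_forward(net, rand_fmap(90, 96, 1, 3)), "divisible by 16")
  expect_error(nn_forward(net, rand_fmap(96, 96, 1, 4)), "expected 3")
})

test_that("all six ablation configurations build, run and take a training step", {
  batch <- list(x = rand_fmap(32, 32, 2, 3, seed = 64),
                y = array(rbinom(32 * 32 * 2 * 2, 1, 0.3), c(32, 32, 2, 2)))
  for (fl in ablation_grid) {
    cfg <- network_config(base_width = 4, depth = 3, seed = 65,
                          use_residual = fl[1], use_hga = fl[2], use_msfe = fl[3])
    net <- rheu_net(cfg)
    suppressWarnings(p <- nn_forward(net, batch$x, training = TRUE))
    expect_identical(dim(p), c(32L, 32L, 2L, 2L))
    g <- rheunet:::bce_dice_loss_grad(p, batch$y)
    nn_backward(net, g)
    params <- nn_parameters(net)
    for (pp in params) {
      gr <- pp$env[[paste0("g", pp$name)]]
      expect_true(is.null(gr) || all(is.finite(gr)))
    }
    opt <- rheunet:::adam_step(rheunet:::adam_init(params), params, 1e-4, 1e-5)
    suppressWarnings(p2 <- nn_forward(net, batch$x, training = TRUE))
    expect_false(identical(p, p2))   # the step moved the weights
  }
})

test_that("structural counts follow the ablation flags", {
  base <- network_config(base_width = 4, depth = 4, seed = 66,
                         use_residual = FALSE, use_hga = FALSE, use_msfe = FALSE)
  plain <- rheu_net(base)
  expect_identical(count_modules(plain, "hga"), 0L)
  expect_identical(count_modules(plain, "msfe"), 0L)
  expect_identical(count_modules(plain, "double_conv_block"), 8L)

  base$use_hga <- TRUE
  with_hga <- rheu_net(base)
  expect_identical(count_modules(with_hga, "hga"), 4L)   # one per skip level

  res_cfg <- base
  res_cfg$use_hga <- FALSE
  res_cfg$use_residual <- TRUE
  with_res <- rheu_net(res_cfg)
  expect_identical(count_modules(with_res, "encoder_residual_block"), 4L)
  expect_identical(count_modules(with_res, "decoder_residual_block"), 4L)
  expect_gt(n_parameters(with_res), n_parameters(plain))
})

test_that("predict_masks applies the threshold and tumor-over-liver precedence", {
  p <- array(0, c(1, 3, 1, 2))
  p[1, , 1, 1] <- c(0.9, 0.9, 0.1)   # liver channel
  p[1, , 1, 2] <- c(0.2, 0.8, 0.1)   # tumor channel
  m <- predict_masks(p)
  expect_identical(as.vector(m$labels), c(1L, 2L, 0L))
  expect_identical(as.vector(m$liver), c(TRUE, TRUE, FALSE))
  expect_identical(as.vector(m$tumor), c(FALSE, TRUE, FALSE))
  expect_error(predict_masks(p, threshold = 0), "threshold")
})

test_that("checkpoints round-trip the configuration and every weight", {
  net <- rheu_net(network_config(base_width = 2, depth = 2, seed = 67))
  x <- rand_fmap(16, 16, 1, 3, seed = 68)
  suppressWarnings(y1 <- nn_forward(net, x))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, extra = list(note = "unit test"))
  ck <- load_checkpoint(path)
  expect_identical(ck$extra$note, "unit test")
  suppressWarnings(y2 <- nn_forward(ck$network, x))
  expect_identical(y1, y2)
  expect_identical(nn_state(net), nn_state(ck$network))
})

test_that("network construction is deterministic in the configuration seed", {
  n1 <- rheu_net(network_config(base_width = 2, depth = 2, seed = 69))
  n2 <- rheu_net(network_config(base_width = 2, depth = 2, seed = 69))
  expect_identical(nn_state(n1), nn_state(n2))
})
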