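# Internal computational-graph engine: forward/backward passes over the block
# graphs produced by build_model(), plus the Adam optimiser.  Tensors are
# (H, W, C) arrays; a batch is a list of such arrays.

BN_EPS <- 1e-3

# TensorFlow-style 'same' padding amounts for one spatial dimension.
pad_same_1d <- function(n, k, stride) {
  out <- ceiling(n / stride)
  tot <- max((out - 1L) * stride + k - n, 0L)
  c(tot %/% 2L, tot - tot %/% 2L)
}

pad_same <- function(dims, k, stride) {
  pv <- pad_same_1d(dims[1L], k, stride)
  ph <- pad_same_1d(dims[2L], k, stride)
  c(pt = pv[1L], pl = ph[1L], pb = pv[2L], pr = ph[2L])
}

relu_ <- function(x) { x[x < 0] <- 0; x }
sigmoid_ <- function(x) 1 / (1 + exp(-x))

apply_act <- function(x, act) {
  switch(act, relu = relu_(x), sigmoid = sigmoid_(x), linear = x)
}

forward_pass <- function(model, xs, training = FALSE, keep_cache = FALSE,
                         momentum = 0.9) {
  acts <- new.env(parent = emptyenv())
  cache <- new.env(parent = emptyenv())
  for (node in model$graph) {
    id <- node$id
    out <- switch(node$op,
      input = lapply(xs, function(x) {
        if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
        x
      }),
      conv = {
        ins <- get(node$inputs, envir = acts)
        p <- model$params[[id]]
        pd <- pad_same(dim(ins[[1L]]), node$k, node$stride)
        z <- lapply(ins, function(a)
          conv_fwd(a, p$W, p$b, node$k, node$stride,
                   pd[1L], pd[2L], pd[3L], pd[4L]))
        if (node$bn) {
          N <- prod(dim(z[[1L]])[1:2]) * length(z)
          if (training) {
            cs <- lapply(z, channel_sums)
            m <- Reduce(`+`, lapply(cs, `[[`, "s")) / N
            v <- pmax(Reduce(`+`, lapply(cs, `[[`, "s2")) / N - m^2, 0)
            p$rmean <- momentum * p$rmean + (1 - momentum) * m
            p$rvar <- momentum * p$rvar + (1 - momentum) * v
            model$params[[id]]$rmean <- p$rmean
            model$params[[id]]$rvar <- p$rvar
          } else {
            m <- p$rmean
            v <- p$rvar
          }
          invstd <- 1 / sqrt(v + BN_EPS)
          a <- p$gamma * invstd
          b <- p$beta - m * a
          code <- switch(node$act, relu = 1L, sigmoid = 2L, 0L)
          y <- lapply(z, function(zi) bn_act_fwd(zi, a, b, code))
          if (keep_cache)
            assign(id, list(z = z, m = m, invstd = invstd, N = N),
                   envir = cache)
          y
        } else lapply(z, apply_act, act = node$act)
      },
      tconv = {
        ins <- get(node$inputs, envir = acts)
        p <- model$params[[id]]
        lapply(ins, function(a) tconv_fwd(a, p$W, p$b, node$k))
      },
      maxpool = {
        ins <- get(node$inputs, envir = acts)
        mp <- lapply(ins, maxpool_fwd)
        if (keep_cache)
          assign(id, lapply(mp, `[[`, "idx"), envir = cache)
        lapply(mp, `[[`, "y")
      },
      upsample = {
        ins <- get(node$inputs, envir = acts)
        lapply(ins, upsample_fwd)
      },
      concat = {
        parts <- lapply(node$inputs, function(i) get(i, envir = acts))
        lapply(seq_along(parts[[1L]]), function(s) {
          pieces <- lapply(parts, `[[`, s)
          d <- dim(pieces[[1L]])
          array(unlist(pieces, use.names = FALSE),
                c(d[1L], d[2L], sum(vapply(pieces, function(a) dim(a)[3L], 1))))
        })
      },
      stop("unknown op: ", node$op))
    assign(id, out, envir = acts)
  }
  list(out = get(model$output_id, envir = acts), acts = acts, cache = cache)
}

backward_pass <- function(model, fw, gout, gout_is_preact = FALSE) {
  acts <- fw$acts
  cache <- fw$cache
  gacc <- new.env(parent = emptyenv())
  assign(model$output_id, gout, envir = gacc)
  pgrads <- list()
  for (node in rev(model$graph)) {
    id <- node$id
    if (!exists(id, envir = gacc) || node$op == "input") next
    g <- get(id, envir = gacc)
    add_grad <- function(dst, gl) {
      if (exists(dst, envir = gacc)) {
        old <- get(dst, envir = gacc)
        gl <- Map(`+`, old, gl)
      }
      assign(dst, gl, envir = gacc)
    }
    switch(node$op,
      conv = {
        y <- get(id, envir = acts)
        p <- model$params[[id]]
        skip_act <- gout_is_preact && id == model$output_id
        if (node$bn) {
          # fused relu + batch-norm backward (all BN blocks use relu)
          cc <- get(id, envir = cache)
          st <- Map(function(gi, yi, zi)
            bn_relu_bwd_stats(gi, yi, zi, cc$m, cc$invstd,
                              node$act == "relu"), g, y, cc$z)
          gbeta <- Reduce(`+`, lapply(st, `[[`, "sg"))
          ggamma <- Reduce(`+`, lapply(st, `[[`, "sgx"))
          c1 <- p$gamma * gbeta / cc$N
          c2 <- p$gamma * ggamma / cc$N
          g <- Map(function(si, zi)
            bn_bwd_gz(si$geff, zi, p$gamma, cc$m, cc$invstd, c1, c2),
            st, cc$z)
          pgrads[[id]]$gamma <- as.numeric(ggamma)
          pgrads[[id]]$beta <- as.numeric(gbeta)
        } else if (!skip_act && node$act == "sigmoid")
          g <- Map(function(gi, yi) gi * yi * (1 - yi), g, y)
        else if (!skip_act && node$act == "relu")
          g <- Map(function(gi, yi) gi * (yi > 0), g, y)
        ins <- get(node$inputs, envir = acts)
        pd <- pad_same(dim(ins[[1L]]), node$k, node$stride)
        gW <- 0; gb <- 0; gx <- vector("list", length(g))
        for (s in seq_along(g)) {
          r <- conv_bwd(ins[[s]], p$W, g[[s]], node$k, node$stride,
                        pd[1L], pd[2L], pd[3L], pd[4L])
          gW <- gW + r$gW; gb <- gb + r$gb; gx[[s]] <- r$gx
        }
        pgrads[[id]]$W <- gW
        pgrads[[id]]$b <- as.numeric(gb)
        add_grad(node$inputs, gx)
      },
      tconv = {
        p <- model$params[[id]]
        ins <- get(node$inputs, envir = acts)
        gW <- 0; gb <- 0; gx <- vector("list", length(g))
        for (s in seq_along(g)) {
          r <- tconv_bwd(ins[[s]], p$W, g[[s]], node$k)
          gW <- gW + r$gW; gb <- gb + r$gb; gx[[s]] <- r$gx
        }
        pgrads[[id]]$W <- gW
        pgrads[[id]]$b <- as.numeric(gb)
        add_grad(node$inputs, gx)
      },
      maxpool = {
        idx <- get(id, envir = cache)
        ins <- get(node$inputs, envir = acts)
        H <- dim(ins[[1L]])[1L]; W <- dim(ins[[1L]])[2L]
        add_grad(node$inputs, Map(function(gi, ix) maxpool_bwd(gi, ix, H, W),
                                  g, idx))
      },
      upsample = {
        add_grad(node$inputs, lapply(g, upsample_bwd))
      },
      concat = {
        off <- 0L
        for (j in seq_along(node$inputs)) {
          nc <- node$in_channels[j]
          part <- lapply(g, function(gi) gi[, , off + seq_len(nc), drop = FALSE])
          add_grad(node$inputs[j], part)
          off <- off + nc
        }
      })
    rm(list = id, envir = gacc)
  }
  pgrads
}

# ---------------------------------------------------------------------------
# Adam optimiser over the model's parameter list.

adam_init <- function(model) {
  st <- list(t = 0L, m = list(), v = list())
  for (id in names(model$params)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      a <- model$params[[id]][[nm]]
      if (!is.null(a)) {
        key <- paste0(id, ".", nm)
        st$m[[key]] <- a * 0
        st$v[[key]] <- a * 0
      }
    }
  }
  st
}

adam_step <- function(model, pgrads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (id in names(pgrads)) {
    for (nm in names(pgrads[[id]])) {
      key <- paste0(id, ".", nm)
      g <- pgrads[[id]][[nm]]
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      model$params[[id]][[nm]] <- model$params[[id]][[nm]] -
        lr * (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
    }
  }
  state
}
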