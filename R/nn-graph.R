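# Minimal static-graph neural network engine.
#
# Tensors are dense R arrays with dim (H, W, C, N). A graph is an ordered list
# of nodes (topological by construction); each node knows its op, inputs,
# static output shape and the names of its trainable parameters. Forward keeps
# every activation so backward can run the reverse sweep; heavy kernels live
# in src/nn_kernels.cpp.

nn_graph <- function() {
  structure(list(nodes = list()), class = "nn_graph")
}

ng_shape <- function(g, name) g$nodes[[name]]$out_shape

same_padding <- function(in_size, k, stride, dil = 1L) {
  eff <- (k - 1L) * dil + 1L
  out <- ceiling(in_size / stride)
  pad <- max((out - 1L) * stride + eff - in_size, 0L)
  c(before = pad %/% 2L, after = pad - pad %/% 2L, out = as.integer(out))
}

ng_add <- function(g, name, op, inputs = character(), ...) {
  if (name %in% names(g$nodes)) stop("duplicate node name: ", name)
  cfg <- list(...)
  node <- list(name = name, op = op, inputs = inputs, cfg = cfg,
               param_names = character())
  ish <- lapply(inputs, function(i) {
    if (is.null(g$nodes[[i]])) stop("unknown input node: ", i)
    g$nodes[[i]]$out_shape
  })
  node$out_shape <- switch(op,
    input = cfg$shape,
    conv = {
      s <- ish[[1]]; st <- cfg$stride %||% 1L; dl <- cfg$dilation %||% 1L
      kh <- cfg$k[1]; kw <- cfg$k[length(cfg$k)]
      node$cfg$kh <- kh; node$cfg$kw <- kw
      if (identical(cfg$padding %||% "same", "same")) {
        ph <- same_padding(s[1], kh, st, dl); pw <- same_padding(s[2], kw, st, dl)
        node$cfg$pt <- ph["before"]; node$cfg$pl <- pw["before"]
        c(ph["out"], pw["out"], cfg$filters)
      } else {
        effh <- (kh - 1L) * dl + 1L; effw <- (kw - 1L) * dl + 1L
        node$cfg$pt <- 0L; node$cfg$pl <- 0L
        c((s[1] - effh) %/% st + 1L, (s[2] - effw) %/% st + 1L, cfg$filters)
      }
    },
    convt = {
      s <- ish[[1]]; k <- cfg$k; st <- cfg$stride
      ho <- s[1] * st; wo <- s[2] * st
      # geometry of the virtual forward conv (output -> input), same padding
      pad <- max((s[1] - 1L) * st + k - ho, 0L)
      node$cfg$pt <- pad %/% 2L
      padw <- max((s[2] - 1L) * st + k - wo, 0L)
      node$cfg$pl <- padw %/% 2L
      c(ho, wo, cfg$filters)
    },
    maxpool = , avgpool = {
      s <- ish[[1]]; k <- cfg$k; st <- cfg$stride %||% 1L
      if (k > min(s[1], s[2]) && identical(cfg$padding %||% "same", "valid"))
        stop("pool kernel larger than input spatial size")
      if (identical(cfg$padding %||% "same", "same")) {
        ph <- same_padding(s[1], k, st); pw <- same_padding(s[2], k, st)
        node$cfg$pt <- ph["before"]; node$cfg$pl <- pw["before"]
        c(ph["out"], pw["out"], s[3])
      } else {
        node$cfg$pt <- 0L; node$cfg$pl <- 0L
        c((s[1] - k) %/% st + 1L, (s[2] - k) %/% st + 1L, s[3])
      }
    },
    bn = , relu = , sigmoid = ish[[1]],
    gap = c(1L, 1L, ish[[1]][3]),
    resize = c(cfg$size[1], cfg$size[2], ish[[1]][3]),
    concat = {
      sp <- ish[[1]][1:2]
      for (s in ish) if (!identical(s[1:2], sp))
        stop("concat inputs disagree on spatial size")
      c(sp, sum(vapply(ish, function(s) s[3], integer(1))))
    },
    zero_branch = ish[[1]],
    stop("unknown op: ", op)
  )
  node$out_shape <- as.integer(node$out_shape)
  if (op == "conv") {
    node$param_names <- paste0(name, c(".w", if (isTRUE(cfg$bias)) ".b"))
  } else if (op == "convt") {
    node$param_names <- paste0(name, c(".w", ".b"))
  } else if (op == "bn") {
    node$param_names <- paste0(name, c(".gamma", ".beta"))
  }
  g$nodes[[name]] <- node
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convenience: conv (no bias) -> batch norm -> ReLU, the pervasive block.
ng_conv_bn_relu <- function(g, name, input, filters, k, stride = 1L,
                            padding = "same", dilation = 1L) {
  g <- ng_add(g, paste0(name, "_conv"), "conv", input, filters = filters,
              k = k, stride = stride, padding = padding, dilation = dilation,
              bias = FALSE)
  g <- ng_add(g, paste0(name, "_bn"), "bn", paste0(name, "_conv"))
  ng_add(g, name, "relu", paste0(name, "_bn"))
}

# He-normal initialization for convolution weights; identity-affine for BN.
ng_init_params <- function(g, seed = 1L) {
  set.seed(as.integer(seed))
  params <- list()
  for (node in g$nodes) {
    cfg <- node$cfg
    if (node$op == "conv") {
      cin <- g$nodes[[node$inputs[1]]]$out_shape[3]
      fan_in <- cfg$kh * cfg$kw * cin
      params[[paste0(node$name, ".w")]] <-
        array(stats::rnorm(cfg$kh * cfg$kw * cin * cfg$filters,
                           sd = sqrt(2 / fan_in)),
              dim = c(cfg$kh, cfg$kw, cin, cfg$filters))
      if (isTRUE(cfg$bias))
        params[[paste0(node$name, ".b")]] <- numeric(cfg$filters)
    } else if (node$op == "convt") {
      cin <- g$nodes[[node$inputs[1]]]$out_shape[3]
      fan_in <- cfg$k * cfg$k * cin
      params[[paste0(node$name, ".w")]] <-
        array(stats::rnorm(cfg$k * cfg$k * cfg$filters * cin,
                           sd = sqrt(2 / fan_in)),
              dim = c(cfg$k, cfg$k, cfg$filters, cin))
      params[[paste0(node$name, ".b")]] <- numeric(cfg$filters)
    } else if (node$op == "bn") {
      ch <- node$out_shape[3]
      params[[paste0(node$name, ".gamma")]] <- rep(1, ch)
      params[[paste0(node$name, ".beta")]] <- rep(0, ch)
    }
  }
  params
}

ng_init_state <- function(g) {
  state <- list()
  for (node in g$nodes) {
    if (node$op == "bn") {
      ch <- node$out_shape[3]
      state[[paste0(node$name, ".rm")]] <- rep(0, ch)
      state[[paste0(node$name, ".rv")]] <- rep(1, ch)
    }
  }
  state
}

ng_n_params <- function(g, params) {
  sum(vapply(params, length, numeric(1)))
}

# Forward pass. Returns activations for every node plus per-node caches and
# (in training mode) updated batch-norm running statistics.
ng_forward <- function(g, params, x, training = FALSE, state = NULL,
                       momentum = 0.99) {
  if (is.null(state)) state <- ng_init_state(g)
  outs <- list(); caches <- list()
  for (node in g$nodes) {
    nm <- node$name; cfg <- node$cfg
    inp <- lapply(node$inputs, function(i) outs[[i]])
    outs[[nm]] <- switch(node$op,
      input = x,
      conv = {
        w <- params[[paste0(nm, ".w")]]
        b <- if (isTRUE(cfg$bias)) params[[paste0(nm, ".b")]] else numeric(0)
        nn_conv_fwd(inp[[1]], w, b, cfg$stride %||% 1L, cfg$stride %||% 1L,
                    cfg$dilation %||% 1L, cfg$pt, cfg$pl,
                    node$out_shape[1], node$out_shape[2])
      },
      convt = {
        nn_convt_fwd(inp[[1]], params[[paste0(nm, ".w")]],
                     params[[paste0(nm, ".b")]], cfg$stride,
                     cfg$pt, cfg$pl, node$out_shape[1], node$out_shape[2])
      },
      bn = {
        r <- nn_bn_fwd(inp[[1]], params[[paste0(nm, ".gamma")]],
                       params[[paste0(nm, ".beta")]],
                       state[[paste0(nm, ".rm")]], state[[paste0(nm, ".rv")]],
                       training, 1e-3)
        caches[[nm]] <- list(mean = r$mean, var = r$var)
        if (training) {
          state[[paste0(nm, ".rm")]] <-
            momentum * state[[paste0(nm, ".rm")]] + (1 - momentum) * r$mean
          state[[paste0(nm, ".rv")]] <-
            momentum * state[[paste0(nm, ".rv")]] + (1 - momentum) * r$var
        }
        r$y
      },
      relu = { y <- inp[[1]]; y[y < 0] <- 0; y },
      sigmoid = 1 / (1 + exp(-inp[[1]])),
      maxpool = {
        r <- nn_maxpool_fwd(inp[[1]], cfg$k, cfg$k, cfg$stride %||% 1L,
                            cfg$stride %||% 1L, cfg$pt, cfg$pl,
                            node$out_shape[1], node$out_shape[2])
        caches[[nm]] <- r$argmax
        r$y
      },
      avgpool = nn_avgpool_fwd(inp[[1]], cfg$k, cfg$k, cfg$stride %||% 1L,
                               cfg$stride %||% 1L, cfg$pt, cfg$pl,
                               node$out_shape[1], node$out_shape[2]),
      gap = {
        d <- dim(inp[[1]])
        y <- apply(inp[[1]], c(3, 4), mean)
        array(y, dim = c(1L, 1L, d[3], d[4]))
      },
      resize = nn_resize_bilinear_fwd(inp[[1]], cfg$size[1], cfg$size[2]),
      concat = {
        d <- dim(inp[[1]])
        chs <- vapply(inp, function(a) dim(a)[3], integer(1))
        y <- array(0, dim = c(d[1], d[2], sum(chs), d[4]))
        at <- 0L
        for (a in inp) {
          y[, , at + seq_len(dim(a)[3]), ] <- a
          at <- at + dim(a)[3]
        }
        y
      },
      zero_branch = array(0, dim = dim(inp[[1]]))
    )
  }
  list(outs = outs, caches = caches, state = state)
}

# Reverse sweep. `seed_grads` is a named list of gradients w.r.t. node outputs
# (usually just the head). Returns parameter gradients.
ng_backward <- function(g, params, fwd, seed_grads) {
  outs <- fwd$outs; caches <- fwd$caches
  grads_out <- seed_grads
  pgrads <- list()
  add_g <- function(store, nm, val) {
    if (is.null(store[[nm]])) store[[nm]] <- val else store[[nm]] <- store[[nm]] + val
    store
  }
  for (node in rev(g$nodes)) {
    nm <- node$name
    gy <- grads_out[[nm]]
    if (is.null(gy)) next
    cfg <- node$cfg
    inps <- node$inputs
    switch(node$op,
      input = NULL,
      conv = {
        x <- outs[[inps[1]]]
        w <- params[[paste0(nm, ".w")]]
        r <- nn_conv_bwd(x, w, gy, cfg$stride %||% 1L, cfg$stride %||% 1L,
                         cfg$dilation %||% 1L, cfg$pt, cfg$pl,
                         isTRUE(cfg$bias))
        grads_out <- add_g(grads_out, inps[1], r$gx)
        pgrads <- add_g(pgrads, paste0(nm, ".w"), r$gw)
        if (isTRUE(cfg$bias)) pgrads <- add_g(pgrads, paste0(nm, ".b"), r$gb)
      },
      convt = {
        x <- outs[[inps[1]]]
        r <- nn_convt_bwd(x, params[[paste0(nm, ".w")]], gy, cfg$stride,
                          cfg$pt, cfg$pl)
        grads_out <- add_g(grads_out, inps[1], r$gx)
        pgrads <- add_g(pgrads, paste0(nm, ".w"), r$gw)
        pgrads <- add_g(pgrads, paste0(nm, ".b"), r$gb)
      },
      bn = {
        x <- outs[[inps[1]]]
        cc <- caches[[nm]]
        r <- nn_bn_bwd(x, params[[paste0(nm, ".gamma")]], cc$mean, cc$var,
                       gy, 1e-3, TRUE)
        grads_out <- add_g(grads_out, inps[1], r$gx)
        pgrads <- add_g(pgrads, paste0(nm, ".gamma"), r$ggamma)
        pgrads <- add_g(pgrads, paste0(nm, ".beta"), r$gbeta)
      },
      relu = {
        y <- outs[[nm]]
        grads_out <- add_g(grads_out, inps[1], gy * (y > 0))
      },
      sigmoid = {
        y <- outs[[nm]]
        grads_out <- add_g(grads_out, inps[1], gy * y * (1 - y))
      },
      maxpool = {
        xd <- dim(outs[[inps[1]]])
        grads_out <- add_g(grads_out, inps[1],
                           nn_maxpool_bwd(gy, caches[[nm]], xd))
      },
      avgpool = {
        xd <- dim(outs[[inps[1]]])
        grads_out <- add_g(grads_out, inps[1],
                           nn_avgpool_bwd(gy, xd, cfg$k, cfg$k,
                                          cfg$stride %||% 1L,
                                          cfg$stride %||% 1L, cfg$pt, cfg$pl))
      },
      gap = {
        xd <- dim(outs[[inps[1]]])
        gx <- array(0, dim = xd)
        per <- gy / (xd[1] * xd[2])
        for (n in seq_len(xd[4]))
          for (c in seq_len(xd[3]))
            gx[, , c, n] <- per[1, 1, c, n]
        grads_out <- add_g(grads_out, inps[1], gx)
      },
      resize = {
        xd <- dim(outs[[inps[1]]])
        grads_out <- add_g(grads_out, inps[1],
                           nn_resize_bilinear_bwd(gy, xd))
      },
      concat = {
        at <- 0L
        for (i in inps) {
          ch <- dim(outs[[i]])[3]
          gi <- gy[, , at + seq_len(ch), , drop = FALSE]
          grads_out <- add_g(grads_out, i, gi)
          at <- at + ch
        }
      },
      zero_branch = NULL
    )
    grads_out[[nm]] <- NULL  # free memory as we go
  }
  pgrads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, opt, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  corr1 <- 1 - beta1^opt$t
  corr2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / corr1) / (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(params = params, opt = opt)
}
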