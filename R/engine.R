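## Batched forward and analytic backward pass for the combined model.
## Instances are grouped by meta-path length so the GRU runs as dense
## matrix algebra; gradients are accumulated exactly (verified against
## finite differences in the test suite).

.addB <- function(M, b) M + rep(b, each = nrow(M))

## Meta-path cache: for every miRNA node, all admissible bounded simple
## paths grouped by length and terminal disease, with per-row type ids.
.buildPathCache <- function(net, config) {
  m <- sum(net@nodeType == "M")
  types <- typeVocabulary(config$lMax, config$mdIntermediate)
  cache <- vector("list", m)
  for (r in seq_len(m)) {
    paths <- .pathsFrom(net, r, config$lMax, config$allowRevisit)
    perLen <- vector("list", config$lMax)
    for (l in seq_len(config$lMax)) {
      p <- paths[[l]]
      if (is.null(p) || !nrow(p)) next
      endsD <- net@nodeType[p[, l + 1L]] == "D"
      p <- p[endsD, , drop = FALSE]
      p <- .admissibleRows(net, p, config$mdIntermediate)
      if (!nrow(p)) next
      tl <- matrix(net@nodeType[p], nrow(p))
      tstr <- apply(tl, 1L, paste, collapse = "")
      tid <- match(tstr, types)
      byEnd <- split(seq_len(nrow(p)), p[, l + 1L])
      perLen[[l]] <- list(mat = p, type = tid, byEnd = byEnd)
    }
    cache[[r]] <- perLen
  }
  list(perMirna = cache, types = types, lMax = config$lMax, m = m)
}

## Assemble per-length instance groups for a set of (r, d) pairs.
## Returns list(groups = per-length list(idx, pair, type), nInst).
.assembleBatch <- function(pathCache, r, d, m) {
  lMax <- pathCache$lMax
  groups <- list()
  for (l in seq_len(lMax)) {
    idx <- vector("list", length(r))
    pair <- vector("list", length(r))
    type <- vector("list", length(r))
    for (b in seq_along(r)) {
      pl <- pathCache$perMirna[[r[b]]][[l]]
      if (is.null(pl)) next
      rows <- pl$byEnd[[as.character(m + d[b])]]
      if (is.null(rows)) next
      idx[[b]] <- pl$mat[rows, , drop = FALSE]
      pair[[b]] <- rep.int(b, length(rows))
      type[[b]] <- pl$type[rows]
    }
    keep <- !vapply(idx, is.null, logical(1))
    if (!any(keep)) next
    groups[[length(groups) + 1L]] <- list(
      idx = do.call(rbind, idx[keep]),
      pair = unlist(pair[keep], use.names = FALSE),
      type = unlist(type[keep], use.names = FALSE))
  }
  list(groups = groups,
       nInst = sum(vapply(groups, function(g) nrow(g$idx), integer(1))))
}

## Full forward (and optional backward) pass over one batch.
##   fd: list(SM, SD, m, n); batch: list(r, d, y, groups)
## Returns losses, scores and (if wantGrads) a gradient list matching the
## parameter list.
.forwardBackward <- function(params, fd, batch, config,
                             train = FALSE, wantGrads = FALSE) {
  Z <- config$Z; X <- config$X; K <- config$K
  q <- config$q; lam <- config$lambda; wd <- config$weightDecay
  usePair <- isTRUE(config$usePair)
  B <- length(batch$r)
  y <- batch$y
  nT <- ncol(params$attp)
  m <- fd$m

  HM <- fd$SM %*% t(params$Wr)
  HD <- fd$SD %*% t(params$Wd)
  HG <- rbind(HM, HD)

  ## ----- pair branch -----
  if (usePair) {
    hr <- HM[batch$r, , drop = FALSE]
    hd <- HD[batch$d, , drop = FALSE]
    C <- cbind(hr, hd, hr * hd, hr + hd)
    A1 <- .addB(C %*% params$W1, params$b1)
    H1a <- pmax(A1, 0)
    mask1 <- NULL
    if (q > 0) {
      if (train) {
        mask1 <- matrix(stats::rbinom(length(H1a), 1L, 1 - q), nrow(H1a))
        H1d <- H1a * mask1
      } else H1d <- (1 - q) * H1a
    } else H1d <- H1a
    G <- .addB(H1d %*% params$W2, params$b2)
    A2 <- .addB(G %*% params$V1, params$c1)
    P1 <- pmax(A2, 0)
    logitN <- as.numeric(P1 %*% params$v2) + params$c2
    lossN <- .bceFromLogits(logitN, y)
  } else {
    G <- matrix(0, B, X)
    lossN <- 0
  }

  ## ----- node (meta-path) branch -----
  groupCaches <- list()
  pooledList <- list()
  instPair <- integer()
  instType <- integer()
  for (gi in seq_along(batch$groups)) {
    grp <- batch$groups[[gi]]
    Tn <- ncol(grp$idx)
    nI <- nrow(grp$idx)
    Xin <- lapply(seq_len(Tn), function(t) HG[grp$idx[, t], , drop = FALSE])
    hPrev <- matrix(0, nI, X)
    steps <- vector("list", Tn)
    S <- vector("list", Tn)
    for (t in seq_len(Tn)) {
      az <- .addB(Xin[[t]] %*% params$Wzx + hPrev %*% params$Wzh, params$bz)
      z <- .sigmoid(az)
      ar <- .addB(Xin[[t]] %*% params$Wrx + hPrev %*% params$Wrh, params$br)
      r <- .sigmoid(ar)
      rh <- r * hPrev
      ag <- .addB(Xin[[t]] %*% params$Whx + rh %*% params$Whh, params$bh)
      g <- tanh(ag)
      maskT <- NULL
      if (q > 0) {
        if (train) {
          maskT <- matrix(stats::rbinom(length(g), 1L, 1 - q), nI)
          gd <- g * maskT
        } else gd <- (1 - q) * g
      } else gd <- g
      h <- z * hPrev + (1 - z) * gd
      steps[[t]] <- list(z = z, r = r, g = g, gd = gd, mask = maskT,
                         hPrev = hPrev, rh = rh)
      S[[t]] <- h
      hPrev <- h
    }
    ## multi-head attentive pooling
    pooled <- matrix(0, nI, X)
    attCache <- vector("list", K)
    for (k in seq_len(K)) {
      Lk <- vapply(seq_len(Tn), function(t)
        as.numeric(S[[t]] %*% params$M[, k]), numeric(nI))
      Lk <- matrix(Lk, nI, Tn)
      Ak <- .rowSoftmax(Lk)
      for (t in seq_len(Tn)) pooled <- pooled + (Ak[, t] * S[[t]]) / K
      attCache[[k]] <- Ak
    }
    groupCaches[[gi]] <- list(steps = steps, S = S, att = attCache,
                              Xin = Xin, idx = grp$idx, Tn = Tn, nI = nI)
    pooledList[[gi]] <- pooled
    instPair <- c(instPair, grp$pair)
    instType <- c(instType, grp$type)
  }
  N <- length(instPair)

  Hnode <- matrix(0, B, X)
  fusion <- NULL
  if (N > 0L) {
    Pm <- do.call(rbind, pooledList)
    eAttMat <- t(params$attp)[instType, , drop = FALSE]
    eraw <- rowSums(Pm * eAttMat)
    eAct <- eraw > 0
    e <- eraw * eAct
    gid <- (instPair - 1) * nT + instType
    beta <- .segmentSoftmax(e, gid)
    Uagg <- rowsum(beta * Pm, gid)
    ugid <- as.numeric(rownames(Uagg))
    pairOf <- (ugid - 1) %/% nT + 1
    typeOf <- (ugid - 1) %% nT + 1
    V <- .sigmoid(Uagg)
    tAttMat <- t(params$attP)[typeOf, , drop = FALSE]
    wraw <- rowSums(V * tAttMat)
    wAct <- wraw > 0
    wv <- wraw * wAct
    gamma <- .segmentSoftmax(wv, pairOf)
    Hagg <- rowsum(gamma * V, pairOf)
    Hnode[as.integer(rownames(Hagg)), ] <- Hagg
    fusion <- list(Pm = Pm, eAttMat = eAttMat, eAct = eAct, gid = gid,
                   beta = beta, ugid = ugid, pairOf = pairOf,
                   typeOf = typeOf, V = V, tAttMat = tAttMat,
                   wAct = wAct, gamma = gamma)
  }

  ## ----- combined scoring head -----
  inp <- cbind(Hnode, G)
  logitM <- as.numeric(inp %*% params$wc) + params$bc
  lossM <- .bceFromLogits(logitM, y)
  lossReg <- wd * sum(vapply(.decayedParams, function(p)
    sum(params[[p]]^2), numeric(1)))
  total <- lossN + lam * lossM + (1 - lam) * lossReg
  scores <- .sigmoid(logitM)

  res <- list(lossN = lossN, lossM = lossM, lossReg = lossReg,
              total = total, scores = scores)
  if (!wantGrads) return(res)

  ## ----- backward -----
  gr <- lapply(params, function(p) array(0, dim = if (is.null(dim(p)))
    length(p) else dim(p)))
  for (nm in names(params))
    if (is.null(dim(params[[nm]]))) gr[[nm]] <- numeric(length(params[[nm]]))
  gr$bc <- 0; gr$c2 <- 0
  dHG <- matrix(0, m + fd$n, Z)

  dlogitM <- lam * (scores - y) / B
  gr$wc <- as.numeric(t(inp) %*% dlogitM)
  gr$bc <- sum(dlogitM)
  dinp <- outer(dlogitM, params$wc)
  dHnode <- dinp[, seq_len(X), drop = FALSE]
  dGhead <- dinp[, X + seq_len(X), drop = FALSE]

  if (N > 0L) {
    fu <- fusion
    dHrows <- dHnode[fu$pairOf, , drop = FALSE]
    dgamma <- rowSums(dHrows * fu$V)
    dV <- fu$gamma * dHrows
    dwv <- .segmentSoftmaxGrad(fu$gamma, dgamma, fu$pairOf)
    dwraw <- dwv * fu$wAct
    aggT <- rowsum(dwraw * fu$V, fu$typeOf)
    gr$attP[, as.integer(rownames(aggT))] <-
      gr$attP[, as.integer(rownames(aggT)), drop = FALSE] + t(aggT)
    dV <- dV + dwraw * fu$tAttMat
    dU <- dV * fu$V * (1 - fu$V)
    gRow <- match(fu$gid, fu$ugid)
    dBP <- dU[gRow, , drop = FALSE]
    dbeta <- rowSums(dBP * fu$Pm)
    dPm <- fu$beta * dBP
    de <- .segmentSoftmaxGrad(fu$beta, dbeta, fu$gid)
    deact <- de * fu$eAct
    aggp <- rowsum(deact * fu$Pm, instType)
    gr$attp[, as.integer(rownames(aggp))] <-
      gr$attp[, as.integer(rownames(aggp)), drop = FALSE] + t(aggp)
    dPm <- dPm + deact * fu$eAttMat

    ## per-group attention + GRU backward
    offset <- 0L
    for (gi in seq_along(groupCaches)) {
      gc <- groupCaches[[gi]]
      nI <- gc$nI; Tn <- gc$Tn
      dpool <- dPm[offset + seq_len(nI), , drop = FALSE]
      offset <- offset + nI
      dS <- lapply(seq_len(Tn), function(t) matrix(0, nI, X))
      for (k in seq_len(K)) {
        Ak <- gc$att[[k]]
        dAk <- matrix(0, nI, Tn)
        for (t in seq_len(Tn)) {
          dAk[, t] <- rowSums(dpool * gc$S[[t]]) / K
          dS[[t]] <- dS[[t]] + (Ak[, t] * dpool) / K
        }
        dLk <- Ak * (dAk - rowSums(Ak * dAk))
        for (t in seq_len(Tn)) {
          dS[[t]] <- dS[[t]] + outer(dLk[, t], params$M[, k])
          gr$M[, k] <- gr$M[, k] + colSums(gc$S[[t]] * dLk[, t])
        }
      }
      carry <- matrix(0, nI, X)
      for (t in rev(seq_len(Tn))) {
        st <- gc$steps[[t]]
        dh <- dS[[t]] + carry
        dz <- dh * (st$hPrev - st$gd)
        dcarry <- dh * st$z
        dgd <- dh * (1 - st$z)
        dg <- if (q > 0) {
          if (train) dgd * st$mask else (1 - q) * dgd
        } else dgd
        dag <- dg * (1 - st$g^2)
        daz <- dz * st$z * (1 - st$z)
        dRH <- dag %*% t(params$Whh)
        dr <- dRH * st$hPrev
        dcarry <- dcarry + dRH * st$r
        dar <- dr * st$r * (1 - st$r)
        Xt <- gc$Xin[[t]]
        gr$Wzx <- gr$Wzx + t(Xt) %*% daz
        gr$Wzh <- gr$Wzh + t(st$hPrev) %*% daz
        gr$bz <- gr$bz + colSums(daz)
        gr$Wrx <- gr$Wrx + t(Xt) %*% dar
        gr$Wrh <- gr$Wrh + t(st$hPrev) %*% dar
        gr$br <- gr$br + colSums(dar)
        gr$Whx <- gr$Whx + t(Xt) %*% dag
        gr$Whh <- gr$Whh + t(st$rh) %*% dag
        gr$bh <- gr$bh + colSums(dag)
        dX <- daz %*% t(params$Wzx) + dar %*% t(params$Wrx) +
          dag %*% t(params$Whx)
        dcarry <- dcarry + daz %*% t(params$Wzh) + dar %*% t(params$Wrh)
        dHG <- .scatterAddRows(dHG, gc$idx[, t], dX)
        carry <- dcarry
      }
    }
  }

  if (usePair) {
    dlogitN <- (.sigmoid(logitN) - y) / B
    gr$v2 <- as.numeric(t(P1) %*% dlogitN)
    gr$c2 <- sum(dlogitN)
    dP1 <- outer(dlogitN, params$v2)
    dA2 <- dP1 * (A2 > 0)
    gr$V1 <- t(G) %*% dA2
    gr$c1 <- colSums(dA2)
    dG <- dGhead + dA2 %*% t(params$V1)
    gr$W2 <- t(H1d) %*% dG
    gr$b2 <- colSums(dG)
    dH1d <- dG %*% t(params$W2)
    dH1a <- if (q > 0) {
      if (train) dH1d * mask1 else (1 - q) * dH1d
    } else dH1d
    dA1 <- dH1a * (A1 > 0)
    gr$W1 <- t(C) %*% dA1
    gr$b1 <- colSums(dA1)
    dC <- dA1 %*% t(params$W1)
    i1 <- seq_len(Z)
    dhr <- dC[, i1, drop = FALSE] + dC[, 2 * Z + i1, drop = FALSE] * hd +
      dC[, 3 * Z + i1, drop = FALSE]
    dhd <- dC[, Z + i1, drop = FALSE] +
      dC[, 2 * Z + i1, drop = FALSE] * hr + dC[, 3 * Z + i1, drop = FALSE]
    dHG <- .scatterAddRows(dHG, batch$r, dhr)
    dHG <- .scatterAddRows(dHG, m + batch$d, dhd)
  }

  gr$Wr <- unname(gr$Wr + t(dHG[seq_len(m), , drop = FALSE]) %*% fd$SM)
  gr$Wd <- unname(gr$Wd +
                  t(dHG[m + seq_len(fd$n), , drop = FALSE]) %*% fd$SD)

  if (wd > 0) {
    for (p in .decayedParams)
      gr[[p]] <- gr[[p]] + 2 * wd * (1 - lam) * params[[p]]
  }
  res$grads <- gr
  res
}
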