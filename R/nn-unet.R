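# Two-level U-Net used by both the frame-analysis and temporal-context
# networks: 3x3 convolutions + ELU, channel widths (f, 2f, 4f) down the
# encoder, 2x2 max pooling, x2 nearest-neighbour upsampling and skip
# concatenations. Input spatial size must be divisible by 4.

unetInit <- function(cin, f) {
  list(
    e1a = convInit(cin, f), e1b = convInit(f, f),
    e2a = convInit(f, 2 * f), e2b = convInit(2 * f, 2 * f),
    e3a = convInit(2 * f, 4 * f), e3b = convInit(4 * f, 4 * f),
    d2a = convInit(6 * f, 2 * f), d2b = convInit(2 * f, 2 * f),
    d1a = convInit(3 * f, f), d1b = convInit(f, f)
  )
}

catChannels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3], da[4]))
  out[seq_len(da[1]), , , ] <- a
  out[da[1] + seq_len(db[1]), , , ] <- b
  out
}

unetFw <- function(x, P) {
  c1 <- eluFw(convFw(x, P$e1a));  e1 <- eluFw(convFw(c1, P$e1b))
  p1 <- cpp_maxpool(e1, dim(e1))
  c2 <- eluFw(convFw(p1$y, P$e2a)); e2 <- eluFw(convFw(c2, P$e2b))
  p2 <- cpp_maxpool(e2, dim(e2))
  c3 <- eluFw(convFw(p2$y, P$e3a)); e3 <- eluFw(convFw(c3, P$e3b))
  u2 <- cpp_upsample2(e3, dim(e3))
  m2 <- catChannels(u2, e2)
  c4 <- eluFw(convFw(m2, P$d2a)); d2 <- eluFw(convFw(c4, P$d2b))
  u1 <- cpp_upsample2(d2, dim(d2))
  m1 <- catChannels(u1, e1)
  c5 <- eluFw(convFw(m1, P$d1a)); d1 <- eluFw(convFw(c5, P$d1b))
  list(out = d1,
       cache = list(x = x, c1 = c1, e1 = e1, p1 = p1, c2 = c2, e2 = e2,
                    p2 = p2, c3 = c3, e3 = e3, m2 = m2, c4 = c4, d2 = d2,
                    m1 = m1, c5 = c5, d1 = d1))
}

unetBw <- function(dout, P, cache) {
  G <- list()
  bwConv <- function(name, xin, act, dact) {
    d <- eluBw(act, dact)
    r <- convBw(xin, P[[name]], d)
    G[[name]] <<- list(W = r$dW, b = r$db, k = 0)
    r$dx
  }
  dc5 <- bwConv("d1b", cache$c5, cache$d1, dout)
  dm1 <- bwConv("d1a", cache$m1, cache$c5, dc5)
  fU1 <- dim(cache$d2)[1]  # channels of u1 = channels of d2
  du1 <- dm1[seq_len(fU1), , , , drop = FALSE]
  de1 <- dm1[fU1 + seq_len(dim(cache$e1)[1]), , , , drop = FALSE]
  dd2 <- cpp_upsample2_bw(du1, dim(cache$d2))
  dc4 <- bwConv("d2b", cache$c4, cache$d2, dd2)
  dm2 <- bwConv("d2a", cache$m2, cache$c4, dc4)
  fU2 <- dim(cache$e3)[1]  # channels of u2 = channels of e3
  du2 <- dm2[seq_len(fU2), , , , drop = FALSE]
  de2extra <- dm2[fU2 + seq_len(dim(cache$e2)[1]), , , , drop = FALSE]
  de3 <- cpp_upsample2_bw(du2, dim(cache$e3))
  dc3 <- bwConv("e3b", cache$c3, cache$e3, de3)
  dp2 <- bwConv("e3a", cache$p2$y, cache$c3, dc3)
  de2 <- cpp_maxpool_bw(dp2, cache$p2$idx, dim(cache$e2)) + de2extra
  dc2 <- bwConv("e2b", cache$c2, cache$e2, de2)
  dp1 <- bwConv("e2a", cache$p1$y, cache$c2, dc2)
  de1full <- cpp_maxpool_bw(dp1, cache$p1$idx, dim(cache$e1)) + de1
  dc1 <- bwConv("e1b", cache$c1, cache$e1, de1full)
  dx <- bwConv("e1a", cache$x, cache$c1, dc1)
  list(dx = dx, grads = G[names(P)])
}
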