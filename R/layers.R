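# Minimal neural-network plumbing: parameter initialisation, linear /
# activation primitives with explicit reverse passes, and Adam. Parameters
# and gradients are nested named lists of numeric arrays with identical
# shapes.

lin_init <- function(nin, nout, scale = sqrt(2 / nin)) {
  list(W = matrix(rnorm(nin * nout, sd = scale), nin, nout),
       b = numeric(nout))
}

lin_fwd <- function(X, p) {
  Y <- X %*% p$W
  Y + rep(p$b, each = nrow(Y))
}

# returns list(dX, grad = list(W, b))
lin_bwd <- function(X, p, dY) {
  list(dX = dY %*% t(p$W),
       grad = list(W = crossprod(X, dY), b = colSums(dY)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}
relu_bwd <- function(x, dy) dy * (x > 0)

# elementwise tanh with cached output
tanh_bwd <- function(y, dy) dy * (1 - y^2)

# --- tree utilities over nested parameter lists ---------------------------

param_map <- function(p, f) {
  if (is.list(p)) lapply(p, param_map, f = f) else f(p)
}

param_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(param_map2, a, b, MoreArgs = list(f = f),
                  SIMPLIFY = FALSE)
    out
  } else {
    f(a, b)
  }
}

param_zeros <- function(p) param_map(p, function(x) x * 0)

param_add <- function(a, b) param_map2(a, b, `+`)

param_count <- function(p) {
  if (is.list(p)) sum(vapply(p, param_count, numeric(1))) else length(p)
}

param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE)
  else as.numeric(p)
}

param_unflatten <- function(template, v) {
  pos <- 0
  rec <- function(p) {
    if (is.list(p)) return(lapply(p, rec))
    n <- length(p)
    out <- p
    out[] <- v[(pos + 1):(pos + n)]
    pos <<- pos + n
    out
  }
  rec(template)
}

# --- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = param_zeros(params), v = param_zeros(params), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- param_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- param_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- param_map2(state$m, state$v,
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- param_map2(params, upd, `-`)
  list(params = params, state = state)
}
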