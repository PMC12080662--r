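# Canonical table of dynamic paths for a model with variables `vars`
# (vars[1] is the "stress" side by convention).  Lag-1 paths are the full
# cross-lagged grid; lag-0 paths depend on the mode:
#   covariance : no directed lag-0 path (residual covariance, K = 2 only)
#   x_to_y     : directed lag-0 paths vars[1] -> each other variable
#   y_to_x     : directed lag-0 paths each other variable -> vars[1]
# Path labels look like "lag1:mchr->stress" and "lag0:mchr->stress".
make_path_table <- function(vars, lag0_mode) {
  K <- length(vars)
  lag1 <- expand.grid(out = seq_len(K), pred = seq_len(K))
  tab <- data.frame(type = "lag1", out = lag1$out, pred = lag1$pred)
  if (lag0_mode == "x_to_y") {
    tab <- rbind(tab, data.frame(type = "lag0", out = 2:K, pred = 1L))
  } else if (lag0_mode == "y_to_x") {
    tab <- rbind(tab, data.frame(type = "lag0", out = 1L, pred = 2:K))
  } else if (lag0_mode != "covariance") {
    stop("unknown lag0_mode: ", lag0_mode, call. = FALSE)
  }
  tab$label <- paste0(tab$type, ":", vars[tab$pred], "->", vars[tab$out])
  tab
}

path_label <- function(type, pred, out) paste0(type, ":", pred, "->", out)

# spectral radius of the VAR(1) companion matrix implied by (B1, B0)
companion_radius <- function(B1, B0 = NULL) {
  K <- nrow(B1)
  if (is.null(B0)) B0 <- matrix(0, K, K)
  A <- solve(diag(K) - B0, B1)
  max(Mod(eigen(A, only.values = TRUE)$values))
}
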