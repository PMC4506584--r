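# internal numerical helpers

# symmetric positive-definite inverse with explicit checks; tolerance on
# the smallest eigenvalue is 1e-10 (relative to the largest)
.pd_inverse <- function(V, label = "V") {
  if (!is.matrix(V) || nrow(V) != 4L || ncol(V) != 4L)
    stop(label, " must be a 4x4 matrix", call. = FALSE)
  if (max(abs(V - t(V))) > 1e-8)
    stop(label, " is not symmetric", call. = FALSE)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(abs(ev)))
    stop(label, " is not positive definite (smallest eigenvalue ",
         format(min(ev)), "); with hard calls this usually means a zero ",
         "or near-empty genotype cell - consider the jackknife with ",
         "grouping or the haldane zero policy", call. = FALSE)
  ch <- chol((V + t(V)) / 2)
  chol2inv(ch)
}

.cone_code <- function(cone = c("union", "nonnegative", "nonpositive")) {
  cone <- match.arg(cone)
  c(union = 0L, nonnegative = 1L, nonpositive = 2L)[[cone]]
}

# cell names for 3x3 genotype tables, zero-based indices
.cell_name <- function(l, m) sprintf("(%d,%d)", l, m)

.beta_names <- c("b00", "b01", "b10", "b11")
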