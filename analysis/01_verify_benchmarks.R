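#!/usr/bin/env Rscript
# Verification benchmarks for the morphoelastic shell solver.
#
# 1. Stress-free growth: a free capsule shell grown to g = 2 must octuple its
#    volume with vanishing stress (analytic similarity solution).
# 2. Thick-sphere inflation: the 3D solver against the 1D radial oracle at
#    two resolutions (discretization error must shrink under refinement).
# 3. Linear regime: both solver and oracle against the closed-form Lamé
#    thick-sphere solution at small pressure.
#
# Writes results/benchmarks.csv. Problem sizes are the package defaults for
# these benchmarks (see the methods vignette).

library(faveosim)

dir.create("results", showWarnings = FALSE)
rows <- list()
note <- function(...) cat(sprintf(...), "\n")

## 1 — stress-free growth --------------------------------------------------
mats <- list(epithelium = material_region(1, 0.3))
shell <- make_shell_in_lattice(geometry_params(
  shell_length = 3, shell_thickness = 0.2, n_rings = 0, n_longitudinal = 0,
  target_edge_length = 0.3))
st <- newton_solve(shell, mats, load_program(g_target = 2, p_target = 0,
                                             n_increments = 4))
vr <- deformed_volume(shell, st) / deformed_volume(shell)
smax <- max(cauchy_stress_norms(shell, st, mats, g = 2))
note("[growth] volume ratio %.6f (expected 8), max Cauchy stress %.2e", vr, smax)
rows$growth <- data.frame(benchmark = "stress_free_growth",
                          value = vr, reference = 8,
                          rel_error = abs(vr - 8) / 8)

## 2 — thick-sphere inflation vs radial oracle ------------------------------
mat <- material_region(1, 0.3)
oracle <- solve_radial(radial_problem(0.8, 1, mat, p_inner = -0.05, g = 1))
prog <- load_program(g_target = 1, p_target = -0.05, n_increments = 5)
errs <- vapply(
  list(default = make_sphere_shell(0.8, 1, 0.15, n_radial_layers = 4),
       refined = make_sphere_shell(0.8, 1, 0.12, n_radial_layers = 5)),
  function(s) {
    stx <- newton_solve(s, list(epithelium = mat), prog)
    ids <- sort(unique(as.vector(s$facets$luminal)))
    X <- s$nodes[ids, ]
    ur <- mean(rowSums(stx$U[ids, ] * X) / sqrt(rowSums(X^2)))
    abs(ur - oracle$u_inner) / abs(oracle$u_inner)
  }, 0)
note("[sphere] oracle u_inner %.6f; FEM rel. error %.4f (default) -> %.4f (refined)",
     oracle$u_inner, errs[1], errs[2])
rows$sphere <- data.frame(benchmark = c("sphere_vs_oracle_default",
                                        "sphere_vs_oracle_refined"),
                          value = errs, reference = 0, rel_error = errs)

## 3 — linear regime vs Lamé -----------------------------------------------
q <- 1e-3
u_lame <- lame_thick_sphere_u(0.8, 0.8, 1, 1, 0.3, q)
or_lin <- solve_radial(radial_problem(0.8, 1, mat, -q, 1))
s_lin <- make_sphere_shell(0.8, 1, 0.12, n_radial_layers = 5)
st_lin <- newton_solve(s_lin, list(epithelium = mat),
                       load_program(g_target = 1, p_target = -q,
                                    n_increments = 1))
ids <- sort(unique(as.vector(s_lin$facets$luminal)))
X <- s_lin$nodes[ids, ]
u_fem <- mean(rowSums(st_lin$U[ids, ] * X) / sqrt(rowSums(X^2)))
note("[linear] Lamé %.4e; oracle %.4e (err %.4f); FEM %.4e (err %.4f)",
     u_lame, or_lin$u_inner, abs(or_lin$u_inner - u_lame) / u_lame,
     u_fem, abs(u_fem - u_lame) / u_lame)
rows$linear <- data.frame(
  benchmark = c("linear_lame_oracle", "linear_lame_fem"),
  value = c(or_lin$u_inner, u_fem), reference = u_lame,
  rel_error = abs(c(or_lin$u_inner, u_fem) - u_lame) / u_lame)

out <- do.call(rbind, rows)
rownames(out) <- NULL
write.csv(out, "results/benchmarks.csv", row.names = FALSE)
note("wrote results/benchmarks.csv")
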