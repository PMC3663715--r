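# Reference parameter estimates used across the tests, built in code so the
# suite does not depend on the packaged CSV (which gets its own test).

neg_pars <- function() {
  llv_params(a = 3.949e-2, b = 1.445e-8, x0 = 6.512e5)
}

sirna_pars <- function(name) {
  g <- neg_pars()
  tab <- list(
    ACD = c(c = 2.694e-7, d = 8.087e-2, y0 = 2.947e-4),
    KIF = c(c = 1.784e-7, d = 1.506e-1, y0 = 8.382e-3),
    PLK = c(c = 1.337e-7, d = 9.045e-2, y0 = 2.837e-3),
    VHP = c(c = 2.498e-8, d = 3.091e-7, y0 = 3.458e-4),
    HP  = c(c = 2.243e-8, d = 1.118e-7, y0 = 6.760e-4),
    MP  = c(c = 7.258e-9, d = 6.509e-8, y0 = 2.305e-3))
  v <- tab[[name]]
  llv_params(a = g$a, b = g$b, x0 = g$x0,
             c = v[["c"]], d = v[["d"]], y0 = v[["y0"]])
}

sirna_names <- function() c("ACD", "KIF", "PLK", "VHP", "HP", "MP")

code_panel <- function() {
  pans <- c(list(Neg = neg_pars()),
            setNames(lapply(sirna_names(), sirna_pars), sirna_names()))
  class(pans) <- "llv_panel"
  pans
}

# small-but-sufficient GA settings used throughout the tests
fast_ctrl <- function(seed, population = 40, generations = 50,
                      children = 20) {
  ga_control(population = population, generations = generations,
             children = children, seed = seed)
}
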