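# shared builders for small, fully hand-checkable colonies

default_task <- function(id = "forage", k_tau = 1, R = 10, a = 0.1,
                         c = 0.02, family = "saturating") {
  task_spec(id, k_tau = k_tau, family = family, R = R, a = a, c = c)
}

# two identical tasks: symmetry forces an equal split at equilibrium
twin_tasks <- function(k = 1, R = 10, a = 0.05, c = 0.01) {
  list(task_spec("left", k_tau = k, R = R, a = a, c = c),
       task_spec("right", k_tau = k, R = R, a = a, c = c))
}

# the 4-ant, 2-caste, 2-task colony whose ledger is summed by hand:
#   caste A (E=2): omega = (t1: 4, t2: 2); caste B (E=1): omega = (t2: 3)
#   n = 4, counts (A: 2, B: 2), eps = (t1: 0.25, t2: 0.5)
# assignment (specialists first): B puts 2 ants on t2; A puts 1 on t1,
# 1 idle.  U_t1 = 1*(0.5*4 - 0.1) = 1.9 ; U_t2 = 2*(1*3 - 0.2) = 5.6
# G = 7.5 ; E = 2*2 + 2*1 = 6 ; P = 1.5 ; p = 0.375
hand_colony <- function() {
  tasks <- list(task_spec("t1", k_tau = 0.5, R = 5, a = 0.1, c = 0.1),
                task_spec("t2", k_tau = 1, R = 5, a = 0.1, c = 0.2))
  castes <- list(caste_spec("A", E_basal = 2, omega = c(t1 = 4, t2 = 2)),
                 caste_spec("B", E_basal = 1, omega = c(t2 = 3)))
  state <- colony_state(tasks, castes, n = 4,
                        counts = c(A = 2, B = 2),
                        eps = c(t1 = 0.25, t2 = 0.5))
  list(tasks = tasks, castes = castes, state = state)
}

# random strictly-concave task drawn from the fixture generator's ranges
random_task <- function(id = "t") {
  n_scale <- runif(1, 50, 200)
  kt <- runif(1, 0.3, 1)
  R <- runif(1, 5, 20)
  a <- runif(1, 1.5, 6) / n_scale
  task_spec(id, k_tau = kt, R = R, a = a,
            c = kt * R * a * runif(1, 0.002, 0.02))
}
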