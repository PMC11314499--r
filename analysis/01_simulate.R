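#!/usr/bin/env Rscript
# Generate the synthetic study systems: a metastable discrete chain with
# known transition matrix, Brownian dynamics on a symmetric double well
# (the stand-in for the conformational dynamics of a two-state protein),
# and a toy receptor-ligand bead complex for the energetics stages.
# Writes ground-truth inputs consumed by the later scripts.

suppressPackageStartupMessages(library(allokin))
seed <- 20260923L
dir.create("results", showWarnings = FALSE)
dir.create("results/inputs", showWarnings = FALSE)

# 4-state chain with two metastable blocks
spec <- chain_spec(4, list(1:2, 3:4), p_between = 0.05, seed = seed)
T4 <- make_transition_matrix(spec)
dtraj <- sample_discrete_chain(T4, 100000, seed = split_seed(seed, 1L))
utils::write.csv(as.data.frame(T4), "results/inputs/true_transition_matrix.csv",
                 row.names = FALSE)
utils::write.table(dtraj, "results/inputs/chain_dtraj.txt",
                   row.names = FALSE, col.names = FALSE)
cat(sprintf("chain: 4 states, 2 blocks, %d steps; slowest eigenvalue %.4f\n",
            length(dtraj), sort(Re(eigen(T4)$values), TRUE)[2]))

# Brownian double well (reduced units), plus noise features for TICA
dw <- potential_spec(1, list(-1, 1), barrier_heights = 1.5)
ct <- simulate_brownian(dw, 2000000, dt = 5e-3, seed = split_seed(seed, 2L))
utils::write.table(round(ct$frames[seq(1, nrow(ct$frames), by = 20), , drop = FALSE], 5),
                   "results/inputs/doublewell_traj_strided.txt",
                   row.names = FALSE, col.names = FALSE)
cat(sprintf("double well: %d steps, dt %.0e; fraction in left well %.4f\n",
            nrow(ct$frames), ct$dt, mean(ct$frames[, 1] < 0)))

# toy receptor-ligand complex with a JSON/PDB serialization
sys <- make_toy_complex(12, 4, seed = split_seed(seed, 3L))
write_system_json(sys, "results/inputs/toy_complex.json",
                  pdb_path = "results/inputs/toy_complex.pdb")
cat(sprintf("toy complex: %d receptor + %d ligand beads, net charge %.2e e\n",
            sum(sys$group == "receptor"), sum(sys$group == "ligand"),
            sum(sys$charges)))
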