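# dendsig

Spatial signaling model and molecular-signature classifier of LTP
induction in hippocampal CA1 dendrites.

## What it is for

Different induction protocols — multiple 100 Hz trains, theta-range
stimulation, or weak stimulation paired with the beta-adrenergic agonist
isoproterenol — all produce long-lasting LTP (L-LTP), yet depend on
different kinases. `dendsig` is for computational neuroscientists who
want to explore a mechanistic resolution of that diversity: a
reaction-diffusion model of the postsynaptic signaling network of a CA1
dendrite with spines (calcium, calmodulin, CaMKII, calcineurin, PDE1B,
AC1/AC8, the beta2-adrenergic receptor with Gs-Gi switching, PKA, Epac,
Inhibitor-1/PP1, PDE4, GluA1), the classic stimulation protocols, and a
threshold-crossing classifier built on two *molecular signatures*.

The spine signature sums normalized fold increases of key kinase
activities in the spine,

    S_spine(t) = d_pCaMKII(t)/max_pCaMKII + d_Epac(t)/max_Epac
                 + d_PKA(t)/max_PKA,

and the dendritic signature splits the PKA term into phospho-I1 +
phospho-PDE4 and released Gi-beta-gamma (reporting beta2AR
phosphorylation),

    S_dend(t) = d_Epac/max_Epac + d_pCaMKII/max_pCaMKII
                + d_(pI1+pPDE4)/max_(pI1+pPDE4) + d_Gi/max_Gi,

where each `d_X` is a fold increase over the pre-stimulus baseline and
each `max_X` is the maximum trial-mean peak over the seven control
protocols. A protocol is classified L-LTP when **both** signatures
exceed their calibrated amplitude thresholds for more than 10 s; an
additional single threshold on the fold change of phosphorylated GluA1
(pAMPAR) classifies E-LTP.

The package provides a deterministic compartmental engine (stiff sparse
ODEs; the desk-scale workhorse), a mesoscopic stochastic engine
(fixed-timestep tau-leaping with binomially partitioned diffusion jumps,
plus an exact SSA for oracle models), voxelized spine/dendrite
geometries, protocol builders with a Tsodyks-Markram release model for
norepinephrine co-release, calibration routines, and synthetic fixtures
with closed-form oracles.

## Worked example

Equilibrate the model, calibrate the calcium injections, run one
protocol and classify it:

```r
library(dendsig)

m    <- ca1_model()
mesh <- build_mesh(geometry_spec(), resolution = 0.25)
comp <- compartments(mesh)
cfg  <- engine_config("deterministic", equilibration = 3000,
                      sample_interval = 0.5)

eq    <- equilibrate(m, comp, within(cfg, sample_interval <- 25))
calib <- calibrate_calcium(m, comp, cfg, state = eq$state)

# seven control protocols: norms + thresholds + trajectories
cs <- control_suite(m, comp, calib, cfg, state = eq$state)
cs$thresholds
#> <threshold_set> spine [ 1.27 , 1.3 ], dendrite [ 1.61 , 1.65 ],
#>   duration > 10 s, E-LTP pAMPAR fold > 1.97

res <- signature_result(cs$trajs[["4xHFS-80s"]], m, cs$norms,
                        cs$thresholds, t_on = cs$t_on[["4xHFS-80s"]])
res
#> <signature_result> 4xHFS-80s: L-LTP
#>   spine duration >lower/upper: 86/75 s; dendrite: 22.5/11 s;
#>   pAMPAR fold 3.4
```

The printed durations are the times the spine and dendritic signatures
spend above the calibrated lower/upper amplitude thresholds; `L-LTP`
means both compartments exceeded the lower threshold for longer than the
10 s duration threshold, and the pAMPAR fold above its threshold marks
E-LTP. Single-train HFS, by contrast, crosses only the spine threshold
(synaptic tagging without the dendritic signal), and LFS or bath ISO
alone cross neither.

A PKA-blocked variant of any protocol is run by appending `+noPKA`
(e.g. `run_protocol(m, comp, "4xHFS-80s+noPKA", calib, cfg)`), and
antagonist variants by prefixing the drug
(`"Propranolol+4xHFS"`, `"ICI+4xHFS"`, `"Carvedilol+2xHFS"`).

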