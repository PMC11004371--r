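## Shared naming constants for the model topology; this file collates
## first so every other file can use them at load time.

.comp_names <- c("aortic_arch", "systemic_artery", "coronary", "cerebral",
                 "skeletal_muscle", "splanchnic", "extrasplanchnic",
                 "systemic_vein", "thoracic_vein", "pulmonary_artery",
                 "pulmonary_vein")
.arterial_comps <- .comp_names[1:7]
.distal_comps <- .comp_names[3:7]
.chamber_names <- c("la", "lv", "ra", "rv")

## Flow fractions of the five distal systemic beds (coronary, cerebral,
## skeletal muscle, splanchnic, extrasplanchnic); used to split the parallel
## resistance among branches.
.distal_fractions <- c(coronary = 0.05, cerebral = 0.13, skeletal_muscle = 0.22,
                       splanchnic = 0.40, extrasplanchnic = 0.20)
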