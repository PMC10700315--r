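# Reconstruction of the across-site conceptual path model (synthetic-study
# default; swap for your own model file via run_pipeline(dag_file = ...)).
# Directed paths: "cause -> effect". Correlated errors: "a ~~ b".
# Exogenous management descriptors covary by design (the regime is defined
# by stocking rate), so they are tied by correlated errors, not paths.
# Land history is deliberately absent.

management -> abundance
management -> richness
management -> FDisBehavior
management -> FDisMorphology
cattle_density -> abundance
cattle_density -> richness
cattle_density -> FDisBehavior
cattle_density -> FDisMorphology
anthelmintic -> abundance
anthelmintic -> richness
anthelmintic -> FDisBehavior
anthelmintic -> FDisMorphology
climate -> abundance
climate -> richness
climate -> FDisBehavior
climate -> FDisMorphology
climate -> dung_removal
richness -> FDisBehavior
abundance -> dung_removal
richness -> dung_removal
FDisBehavior -> dung_removal
FDisMorphology -> dung_removal

FDisBehavior ~~ FDisMorphology
abundance ~~ richness
management ~~ cattle_density
management ~~ anthelmintic
cattle_density ~~ anthelmintic
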