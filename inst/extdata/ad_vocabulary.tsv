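concept_id	type	preferred_label	synonym
alzheimer-s-disease	DISEASE	Alzheimer's Disease	
alzheimer-s-disease	DISEASE	Alzheimer's Disease	AD
alzheimer-s-disease	DISEASE	Alzheimer's Disease	Alzheimer disease
alzheimer-s-disease	DISEASE	Alzheimer's Disease	Alzheimers disease
alzheimer-s-disease	DISEASE	Alzheimer's Disease	dementia of the Alzheimer type
early-onset-alzheimer-s-disease	DISEASE	Early Onset Alzheimer's Disease	
early-onset-alzheimer-s-disease	DISEASE	Early Onset Alzheimer's Disease	EOAD
early-onset-familial-alzheimer-s-disease	DISEASE	Early Onset Familial Alzheimer's Disease	
familial-alzheimer-s-disease	DISEASE	Familial Alzheimer's Disease	
familial-alzheimer-s-disease	DISEASE	Familial Alzheimer's Disease	FAD
incipient-alzheimer-s-disease	DISEASE	Incipient Alzheimer's Disease	
late-onset-alzheimer-s-disease	DISEASE	Late Onset Alzheimer's Disease	
late-onset-alzheimer-s-disease	DISEASE	Late Onset Alzheimer's Disease	LOAD
late-onset-sporadic-alzheimer-s-disease	DISEASE	Late Onset Sporadic Alzheimer's Disease	
mid-stage-alzheimer-s-disease	DISEASE	Mid-Stage Alzheimer's Disease	
mild-to-moderate-alzheimer-s-disease	DISEASE	Mild-to-Moderate Alzheimer's Disease	
moderate-alzheimer-s-disease	DISEASE	Moderate Alzheimer's Disease	
moderate-to-severe-alzheimer-s-disease	DISEASE	Moderate-to-Severe Alzheimer's Disease	
sporadic-alzheimer-s-disease	DISEASE	Sporadic Alzheimer's Disease	
severe-alzheimer-s-disease	DISEASE	Severe Alzheimer's Disease	
acute-phase-reaction	PATHOLOGICAL_OBSERVATION	Acute-Phase Reaction	
amyloid-deposition	PATHOLOGICAL_OBSERVATION	Amyloid Deposition	
amyloid-deposition	PATHOLOGICAL_OBSERVATION	Amyloid Deposition	amyloid deposits
amyloid-deposition	PATHOLOGICAL_OBSERVATION	Amyloid Deposition	amyloid infiltration
amyloid-deposition	PATHOLOGICAL_OBSERVATION	Amyloid Deposition	abnormal deposition of amyloid plaques
amyloid-deposition	PATHOLOGICAL_OBSERVATION	Amyloid Deposition	amyloid protein deposition
amyloid-fibril-formation	PATHOLOGICAL_OBSERVATION	Amyloid Fibril Formation	
amyloid-fibril-formation	PATHOLOGICAL_OBSERVATION	Amyloid Fibril Formation	amyloid formation
amyloid-fibril-formation	PATHOLOGICAL_OBSERVATION	Amyloid Fibril Formation	amyloid fibrillogenesis
amyloidosis	PATHOLOGICAL_OBSERVATION	Amyloidosis	
asymmetric-cortical-atrophy	PATHOLOGICAL_OBSERVATION	Asymmetric Cortical Atrophy	
blood-brain-barrier-dysfunction	PATHOLOGICAL_OBSERVATION	Blood Brain Barrier Dysfunction	
central-nervous-system-inflammation	PATHOLOGICAL_OBSERVATION	Central Nervous System Inflammation	
cerebral-atrophy	PATHOLOGICAL_OBSERVATION	Cerebral Atrophy	
cerebral-atrophy	PATHOLOGICAL_OBSERVATION	Cerebral Atrophy	brain atrophy
cholinergic-dysfunction	PATHOLOGICAL_OBSERVATION	Cholinergic Dysfunction	
corpus-callosum-atrophy	PATHOLOGICAL_OBSERVATION	Corpus Callosum Atrophy	
dystrophic-neuronal-growth	PATHOLOGICAL_OBSERVATION	Dystrophic Neuronal Growth	
glial-inflammation	PATHOLOGICAL_OBSERVATION	Glial Inflammation	
gliosis	PATHOLOGICAL_OBSERVATION	Gliosis	
glucose-hypometabolism	PATHOLOGICAL_OBSERVATION	Glucose Hypometabolism	
granulovacuolar-degeneration	PATHOLOGICAL_OBSERVATION	Granulovacuolar Degeneration	
hippocampal-neurodegeneration	PATHOLOGICAL_OBSERVATION	Hippocampal Neurodegeneration	
inflammation	PATHOLOGICAL_OBSERVATION	Inflammation	
locus-coeruleus-neuronal-loss	PATHOLOGICAL_OBSERVATION	Locus Coeruleus Neuronal Loss	
mitochondrial-failure	PATHOLOGICAL_OBSERVATION	Mitochondrial Failure	
nerve-degeneration	PATHOLOGICAL_OBSERVATION	Nerve Degeneration	
neuritic-plaque-formation	PATHOLOGICAL_OBSERVATION	Neuritic Plaque Formation	
neurofibrillary-degeneration	PATHOLOGICAL_OBSERVATION	Neurofibrillary Degeneration	
neurofibrillary-lesion	PATHOLOGICAL_OBSERVATION	Neurofibrillary Lesion	
neurofibrillary-tangle-formation	PATHOLOGICAL_OBSERVATION	Neurofibrillary Tangle Formation	
neurofibrillary-tangle-formation	PATHOLOGICAL_OBSERVATION	Neurofibrillary Tangle Formation	neurofibrillary tangles
neurofibrillary-tangle-formation	PATHOLOGICAL_OBSERVATION	Neurofibrillary Tangle Formation	NFT formation
neuroinflammation	PATHOLOGICAL_OBSERVATION	Neuroinflammation	
neuronal-degeneration	PATHOLOGICAL_OBSERVATION	Neuronal Degeneration	
neuronal-degeneration	PATHOLOGICAL_OBSERVATION	Neuronal Degeneration	neurodegeneration
neuronal-dysfunction	PATHOLOGICAL_OBSERVATION	Neuronal Dysfunction	
neuronal-dystrophy	PATHOLOGICAL_OBSERVATION	Neuronal Dystrophy	
neuronal-inclusion-bodies	PATHOLOGICAL_OBSERVATION	Neuronal Inclusion Bodies	
neuronal-lesion	PATHOLOGICAL_OBSERVATION	Neuronal Lesion	
neuronal-loss	PATHOLOGICAL_OBSERVATION	Neuronal Loss	
neuronal-loss	PATHOLOGICAL_OBSERVATION	Neuronal Loss	loss of neurons
neuronal-loss	PATHOLOGICAL_OBSERVATION	Neuronal Loss	neuron loss
neuronal-necrosis	PATHOLOGICAL_OBSERVATION	Neuronal Necrosis	
neuronal-shrinkage	PATHOLOGICAL_OBSERVATION	Neuronal Shrinkage	
occipital-atrophy	PATHOLOGICAL_OBSERVATION	Occipital Atrophy	
oxidative-damage	PATHOLOGICAL_OBSERVATION	Oxidative Damage	
oxidative-stress	PATHOLOGICAL_OBSERVATION	Oxidative Stress	
oxidative-stress	PATHOLOGICAL_OBSERVATION	Oxidative Stress	oxidative stress response
perivascular-amyloidosis	PATHOLOGICAL_OBSERVATION	Perivascular Amyloidosis	
synapse-dysfunction	PATHOLOGICAL_OBSERVATION	Synapse Dysfunction	
synaptic-degeneration	PATHOLOGICAL_OBSERVATION	Synaptic Degeneration	
synaptic-loss	PATHOLOGICAL_OBSERVATION	Synaptic Loss	
synapse-enlargement	PATHOLOGICAL_OBSERVATION	Synapse Enlargement	
tau-deposition	PATHOLOGICAL_OBSERVATION	Tau Deposition	
tau-phosphorylation	PATHOLOGICAL_OBSERVATION	Tau Phosphorylation	
tau-phosphorylation	PATHOLOGICAL_OBSERVATION	Tau Phosphorylation	phosphorylation of tau
tau-phosphorylation	PATHOLOGICAL_OBSERVATION	Tau Phosphorylation	tau hyperphosphorylation
tau-mediated-cytotoxicity	PATHOLOGICAL_OBSERVATION	Tau-Mediated Cytotoxicity	
amygdala	ANATOMICAL_STRUCTURE	Amygdala	
anterior-thalamic-nucleus	ANATOMICAL_STRUCTURE	Anterior Thalamic Nucleus	
basal-nucleus-of-meynert	ANATOMICAL_STRUCTURE	Basal Nucleus of Meynert	
ca1-region	ANATOMICAL_STRUCTURE	CA1 region	
ca1-region	ANATOMICAL_STRUCTURE	CA1 region	CA1
ca2-region	ANATOMICAL_STRUCTURE	CA2 region	
ca2-region	ANATOMICAL_STRUCTURE	CA2 region	CA2
ca3-region	ANATOMICAL_STRUCTURE	CA3 region	
ca3-region	ANATOMICAL_STRUCTURE	CA3 region	CA3
cholinergic-neuron	ANATOMICAL_STRUCTURE	Cholinergic Neuron	
diagonal-band-of-broca	ANATOMICAL_STRUCTURE	Diagonal Band of Broca	
entorhinal-cortex	ANATOMICAL_STRUCTURE	Entorhinal Cortex	
entorhinal-cortex	ANATOMICAL_STRUCTURE	Entorhinal Cortex	entorhinal area
frontal-lobe	ANATOMICAL_STRUCTURE	Frontal Lobe	
frontal-lobe	ANATOMICAL_STRUCTURE	Frontal Lobe	frontal cortex
hippocampus	ANATOMICAL_STRUCTURE	Hippocampus	
hippocampus	ANATOMICAL_STRUCTURE	Hippocampus	hippocampal formation
hippocampus	ANATOMICAL_STRUCTURE	Hippocampus	hippocampal region
inferior-temporal-gyrus	ANATOMICAL_STRUCTURE	Inferior Temporal Gyrus	
left-thalamus	ANATOMICAL_STRUCTURE	Left Thalamus	
locus-coeruleus	ANATOMICAL_STRUCTURE	Locus Coeruleus	
medial-temporal-cortex	ANATOMICAL_STRUCTURE	Medial Temporal Cortex	
parahippocampal-gyrus	ANATOMICAL_STRUCTURE	Parahippocampal Gyrus	
parietal-lobe	ANATOMICAL_STRUCTURE	Parietal Lobe	
prefrontal-cortex	ANATOMICAL_STRUCTURE	Prefrontal Cortex	
septal-nucleus	ANATOMICAL_STRUCTURE	Septal Nucleus	
subiculum	ANATOMICAL_STRUCTURE	Subiculum	
substantia-innominata	ANATOMICAL_STRUCTURE	Substantia Innominata	
superior-temporal-gyrus	ANATOMICAL_STRUCTURE	Superior Temporal Gyrus	
synapse	ANATOMICAL_STRUCTURE	Synapse	
synapse	ANATOMICAL_STRUCTURE	Synapse	synapses
temporal-isocortex	ANATOMICAL_STRUCTURE	Temporal Isocortex	
temporal-lobe	ANATOMICAL_STRUCTURE	Temporal Lobe	
temporal-lobe	ANATOMICAL_STRUCTURE	Temporal Lobe	temporal cortex
thalamus	ANATOMICAL_STRUCTURE	Thalamus	
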