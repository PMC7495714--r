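subject_id	group	measure	region	score
s1	PSP	NFT	globus pallidus	2
s1	PSP	NFT	subthalamic nucleus	3
s1	PSP	NFT	substantia nigra	2
s1	PSP	NFT	red nucleus	1
s1	PSP	NFT	locus coeruleus	2
s1	PSP	NFT	pontine base	3
s1	PSP	NFT	pontine tegmentum	2
s1	PSP	NFT	medulla	1
s1	PSP	NFT	dentate nucleus	2
s1	PSP	NFT	cerebellar white matter	3
s1	PSP	NFT	caudate nucleus	2
s1	PSP	NFT	putamen	1
s1	PSP	NFT	thalamus	2
s1	PSP	NFT	motor cortex	3
s1	PSP	NFT	premotor cortex	2
s1	PSP	NFT	superior frontal cortex	1
s1	PSP	NFT	inferior parietal cortex	2
s1	PSP	NFT	oculomotor nucleus	3
s1	PSP	NFT	inferior olive	2
s1	PSP	NFT	midbrain tectum	1
s1	PSP	CB	globus pallidus	1
s1	PSP	CB	subthalamic nucleus	2
s1	PSP	CB	substantia nigra	1
s1	PSP	CB	red nucleus	2
s1	PSP	CB	locus coeruleus	1
s1	PSP	CB	pontine base	2
s1	PSP	CB	pontine tegmentum	1
s1	PSP	CB	medulla	2
s1	PSP	CB	dentate nucleus	1
s1	PSP	CB	cerebellar white matter	2
s1	PSP	CB	caudate nucleus	1
s1	PSP	CB	putamen	2
s1	PSP	CB	thalamus	1
s1	PSP	CB	motor cortex	2
s1	PSP	CB	premotor cortex	1
s1	PSP	CB	superior frontal cortex	2
s1	PSP	CB	inferior parietal cortex	1
s1	PSP	CB	oculomotor nucleus	2
s1	PSP	CB	inferior olive	NA
s1	PSP	CB	midbrain tectum	NA
s4	PSP	NFT	globus pallidus	3
s4	PSP	NFT	subthalamic nucleus	2
s4	PSP	NFT	substantia nigra	3
s4	PSP	NFT	red nucleus	2
s4	PSP	NFT	locus coeruleus	3
s4	PSP	NFT	pontine base	2
s4	PSP	NFT	pontine tegmentum	3
s4	PSP	NFT	medulla	2
s4	PSP	NFT	dentate nucleus	3
s4	PSP	NFT	cerebellar white matter	2
s4	PSP	NFT	caudate nucleus	3
s4	PSP	NFT	putamen	2
s4	PSP	NFT	thalamus	3
s4	PSP	NFT	motor cortex	2
s4	PSP	NFT	premotor cortex	3
s4	PSP	NFT	superior frontal cortex	2
s4	PSP	NFT	inferior parietal cortex	3
s4	PSP	NFT	oculomotor nucleus	2
s4	PSP	NFT	inferior olive	3
s4	PSP	NFT	midbrain tectum	2
s4	PSP	CB	globus pallidus	NA
s4	PSP	CB	subthalamic nucleus	NA
s4	PSP	CB	substantia nigra	NA
s4	PSP	CB	red nucleus	NA
s4	PSP	CB	locus coeruleus	NA
s4	PSP	CB	pontine base	NA
s4	PSP	CB	pontine tegmentum	NA
s4	PSP	CB	medulla	NA
s4	PSP	CB	dentate nucleus	NA
s4	PSP	CB	cerebellar white matter	NA
s4	PSP	CB	caudate nucleus	NA
s4	PSP	CB	putamen	NA
s4	PSP	CB	thalamus	1
s4	PSP	CB	motor cortex	1
s4	PSP	CB	premotor cortex	1
s4	PSP	CB	superior frontal cortex	1
s4	PSP	CB	inferior parietal cortex	1
s4	PSP	CB	oculomotor nucleus	1
s4	PSP	CB	inferior olive	1
s4	PSP	CB	midbrain tectum	1
s2	CBD	NT	globus pallidus	2
s2	CBD	NT	subthalamic nucleus	2
s2	CBD	NT	substantia nigra	2
s2	CBD	NT	red nucleus	2
s2	CBD	NT	locus coeruleus	2
s2	CBD	NT	pontine base	2
s2	CBD	NT	pontine tegmentum	2
s2	CBD	NT	medulla	2
s2	CBD	NT	dentate nucleus	2
s2	CBD	NT	cerebellar white matter	3
s2	CBD	NT	caudate nucleus	3
s2	CBD	NT	putamen	3
s2	CBD	NT	thalamus	3
s2	CBD	NT	motor cortex	3
s2	CBD	NT	premotor cortex	3
s2	CBD	NT	superior frontal cortex	3
s2	CBD	NT	inferior parietal cortex	3
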