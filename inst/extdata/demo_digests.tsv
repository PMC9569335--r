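file	md5
panel.map.tsv	47037dd9ebc9f58e60bf08a07fed1fc4
panel.geno.tsv	978c0f295373557055af06f37050e2ab
peaks.bed	34c6cbbe04f11ab342574e2e1716c719
peaks.signal.tsv	aa720f9d9847f7039bb459030fcdc5d8
segmentation.bed	3fbd9601baec57b80fa8649faddf3cd3
truth_tau.tsv	0f0476730acb7726b56db415430ca40d
sumstats_disorderA.tsv	028ea11c214583fb0fb2a748fbd1cba1
sumstats_disorderB.tsv	219bddca99293e58c15bf9fe87365f8c
active.bed	693f1214ce5e98ce3468abec04034e31
class_promoter.bed	3806c6b8a8f62af84ecff63e9ffb09a6
class_enhancer.bed	edb756ad3074ebee79f2c5419b50f641
class_genic_enhancer.bed	aa24321c1e06c904aa1b274eea4e9767
ldscores.tsv	9a33cafcda9d5983d60119055d0c1abe
sldsc_results.tsv	32ea51f0e685bbb093ebb2e3c1c2c6e0
leads.tsv	aaa97dad652c9b7aa9887163d60e355d
cheers_results.tsv	ed3ed43b7c6923650bc4f03203269384
cheers_overlaps.tsv	c8f4e4cb53ae5450236be9000c03655e
sharing_cells.tsv	88f10731bc57bc8e05703cd01ea7ca6d
discordant_peaks.tsv	524d9ac448d0de5728707b8ee5464e3a
correlation.json	99c4c44db058bea22c36eeef142b1de5
genes.tsv	692057a266ea830892f5e891f466a1bd
genesets.gmt	9157ae7a9a2740af0b16aff74b575219
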