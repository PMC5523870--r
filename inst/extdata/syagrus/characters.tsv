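char_id	label	kind	states	units	symbol	description
adaxial_fb_extent	Extent of adaxial fiber bundles across the mesophyll	ordinal	absent,under_one_fifth,under_one_third,over_one_third		adf	Adaxial (upper-surface) nonvascular fiber bundles, graded by how far they reach across the mesophyll (over_one_third = more than 1/3 to 1/2 or more)
mesophyll_minor_veins	Mesophyll minor veins	ordinal	absent,few,throughout		mv	Minor veins lying within the mesophyll; few = usually present only at the leaflet tip
marginal_vein_exaggerated	Marginal vein with exaggerated fibrous sheath	ordinal	absent,small,large		vex	Vein with a greatly enlarged fibrous sheath at the margin; large = occupying most of the margin, small = less than half
adaxial_minor_veins	Adaxial minor veins	ordinal	absent,occasional,common		adv	Minor veins adjacent to the adaxial surface
abaxial_minor_veins	Abaxial minor veins	ordinal	absent,few,many		abv	Minor veins adjacent to the abaxial surface
abaxial_fb_alternation	Minor abaxial fiber bundles vs abaxial minor veins	categorical	none,not_alternating,alternating			Whether minor abaxial fiber bundles are present and alternate with the abaxial minor veins
mesophyll_fiber_location	Mesophyll fibers or fiber bundles: location	categorical	none,upper_half,lower_half,scattered			Nonvascular fibers free in the mesophyll and where they sit
adaxial_fb_shape	Shape of most adaxial fiber bundles	categorical	linear,elliptical_oblong,wedge,short_fat_rounded			linear = like skinny icicles; wedge = wedge-shaped fat or skinny icicles
large_adaxial_fb_abundance	Abundance of large adaxial fiber bundles	ordinal	none,occasional,abundant
adaxial_mv_extension	Fibrous extension attaching adaxial minor veins	categorical	small,large
lamina_thickness	Lamina thickness	quantitative		mm
primary_vein_attachment	Primary vein attachment	categorical	unattached,nearly_attached,adaxial_only,both		pv	Surface(s) to which primary veins are attached by fibrous sheath extensions
first_fb_size	Size of the first adaxial fiber bundle near the margin	ordinal	small,medium,large,very_large
minor_vein_attachment	Attachment of secondary and minor veins	categorical	abaxial_only,adaxial_only,girder,unattached		g	girder = attached to both surfaces by narrow fibrous extensions
adaxial_fb_size_alternation	Small adaxial fiber bundles alternating with larger ones	binary
secondary_vein_extension_shape	Shape of the adaxial fibrous extension of the secondary vein	categorical	vase,wine_bottle		sv	vase = short and narrowing; wine_bottle = longer and narrow
abaxial_structures_visibility	Visibility of abaxial fibers, fiber bundles and minor veins	ordinal	none,weak,obvious		abf
anatomy_symmetry	Mirrored versus dorsiventral anatomy	categorical	mirrored,dorsiventral			mirrored = structures on one surface lined up exactly opposite structures on the other
pairs_between_veins	Adaxial fiber bundle / abaxial minor vein pairs between primary and secondary veins	ordinal	one,two,three
marginal_large_fb	Large to extra-large fiber bundle at or near the margin	binary			fb
hypodermal_cell_shape	Adaxial hypodermal cell shape	categorical	rounded_bubble,small_rectangular		h
abaxial_hypodermis_tiny_fibers	Tiny fibers in the abaxial hypodermis	binary
margin_sclerenchyma	Marginal hypodermis with thick sclerenchymous walls	binary
stem_habit	Stem habit	categorical	aerial,subterranean			Non-anatomical: aerial columnar stem versus short underground (acaulescent) stem
abaxial_minor_vein_count	Abaxial minor veins and fiber bundles between larger veins	quantitative				Count between larger veins (see also abaxial_minor_veins)
middle_leaflet_length	Middle leaflet length	quantitative		cm		Non-anatomical leaf measurement
middle_leaflet_width	Middle leaflet width	quantitative		cm		Non-anatomical leaf measurement
abaxial_fb_visibility	Abaxial fiber bundles or fibers	categorical	absent_or_faint,obvious
first_fb_relative	First adaxial fiber bundle relative to the others	categorical	similar,largest
mesophyll_fiber_abundance	Abundance of mesophyll fibers	ordinal	few,many
marginal_vex_bilateral	Very large marginal vein with exaggerated sheath on both surfaces	binary				Exaggerated fibrous sheath developed both adaxially and abaxially
mesophyll_vein_sheath_thickened	Most mesophyll veins with abaxially thickened fibrous sheaths	binary
leaf_orientation	Leaf orientation	categorical	procumbent,spreading			Non-anatomical
leaf_rachis_length	Leaf rachis length	quantitative		cm		Non-anatomical leaf measurement
adaxial_fb_quantity	Quantity of adaxial fiber bundles	ordinal	none,few,many
mesophyll_vein_position	Position of mesophyll minor veins	categorical	upper_half,lower_half			mid-to-upper versus lower half of the mesophyll
mesophyll_differentiation	Mesophyll differentiation	categorical	undifferentiated,differentiated		m	differentiated = split into palisade (mp) and spongy (ms) layers
cuticle_thickness	Cuticle layer	categorical	thin,thick		c	Non-cellular waxy layer (w) over the epidermis (e)
vein_near_margin	Largest vein near the margin	categorical	primary,secondary_or_minor
stem_count	Stem number	categorical	solitary,clustered			Non-anatomical: solitary versus in pairs or clustering
adv_abv_pairing	Pairing of adaxial with abaxial minor veins	categorical	not_paired,paired_apart,paired_touching			paired_touching = paired and nearly touching
marginal_minor_fb	Adaxial and marginal minor fiber bundles	binary			mf
adfb_opposite_abv	Adaxial fiber bundles opposite abaxial minor veins	categorical	usually,not_usually
sclerenchyma_extent	Extent of the sclerenchymous hypodermis	categorical	margin_and_adaxial,margin_only
most_veins_attachment	Attachment of most veins	categorical	one_surface,both			one_surface = attached to either the adaxial or the abaxial surface but not both
abaxial_trichomes	Hairy trichomes on the exterior abaxial surface	binary
pubescence_color	Color of abaxial pubescence	categorical	brown,silvery			Non-anatomical
palisade_layers	Number of palisade mesophyll layers	categorical	one,two_or_three
large_vein_near_tip	Large vein near the tip of the margin	binary
marginal_sheath_thickening	Thickening of the marginal vein fibrous sheath	categorical	not_thickened,adaxial_only,both
adaxial_hypodermis_fiber_layer	Fibers in the adaxial hypodermis	ordinal	absent,occasional,interrupted,continuous		hf	continuous = (nearly) continuous single layer of fiber cells
margin_vein_order	Order of larger veins near the margin	categorical	secondary_first,primary_first			secondary_first = secondary vein near the tip, then minor veins, then the primary vein
adaxial_surface_fiber_abundance	Fibers or fiber bundles along the adaxial surface	categorical	few_or_none,many
abaxial_fb_shape	Shape of abaxial fiber bundles	categorical	flattened,small_rounded
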