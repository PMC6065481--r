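region	group	label
left_cerebrum	region	gm_left
left_cerebrum	inside	wm_left
left_cerebrum	inside	subcortex_left
left_cerebrum	inside	ventricle_left
right_cerebrum	region	gm_right
right_cerebrum	inside	wm_right
right_cerebrum	inside	subcortex_right
right_cerebrum	inside	ventricle_right
cerebrum	region	gm_left
cerebrum	region	gm_right
cerebrum	inside	wm_left
cerebrum	inside	wm_right
cerebrum	inside	subcortex_left
cerebrum	inside	subcortex_right
cerebrum	inside	ventricle_left
cerebrum	inside	ventricle_right
cerebellum	region	gm_cerebellum
cerebellum	inside	wm_cerebellum
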